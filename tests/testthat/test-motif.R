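# Motif-hit classification, cutoff calibration and enrichment statistics.

# deterministic hit-table builder: `confident` hits at p = 1e-7 and
# `unreliable` at p = 1e-5 per species, hitting gene g001, g002, ...
make_hits <- function(confident, unreliable = confident,
                      species = paste0("sp", seq_along(confident))) {
  rows <- lapply(seq_along(species), function(i) {
    n <- confident[i] + unreliable[i]
    data.frame(motif_id = "FLEX",
               sequence_name = sprintf("%s_g%03d", species[i], seq_len(n)),
               start = 50L, stop = 60L, strand = "+", score = 10,
               p_value = rep(c(1e-7, 1e-5), c(confident[i], unreliable[i])),
               species = species[i],
               gene_id = sprintf("%s_g%03d", species[i], seq_len(n)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("hit classification partitions hits and aggregates species counts", {
  # the four-species confident totals of a genome-wide FLEX scan
  hits <- make_hits(c(476, 716, 827, 898), unreliable = c(100, 100, 100, 100))
  cl <- classify_hits(hits, 3e-6)
  expect_equal(cl$total_confident, 2917)
  expect_equal(unname(cl$per_species_confident), c(476, 716, 827, 898))
  expect_equal(sum(cl$per_species_confident), cl$total_confident)
  expect_equal(nrow(cl$confident) + nrow(cl$unreliable), nrow(hits))
  # cutoff at 1 keeps everything; empty input classifies to zero
  expect_equal(classify_hits(hits, 1)$total_confident, nrow(hits))
  expect_equal(classify_hits(hits[0, ], 0.5)$total_confident, 0)
})

test_that("the confident rule is inclusive at the cutoff", {
  hits <- make_hits(1, unreliable = 0)
  hits$p_value <- 3e-6
  expect_equal(classify_hits(hits, 3e-6)$total_confident, 1)
})

test_that("cutoff calibration picks between mixture components and breaks ties stringently", {
  # single candidate is returned as-is
  hits <- make_hits(5)
  expect_equal(calibrate_cutoff(hits, "sp1_g001", "bg_g001",
                                candidate_cutoffs = 2e-6)$cutoff, 2e-6)
  # all-noise input: objective 0 everywhere, most stringent candidate wins
  noise <- make_hits(0, unreliable = 20)
  cal <- calibrate_cutoff(noise, "none_g1", "sp1_g001",
                          candidate_cutoffs = c(1e-4, 1e-6, 1e-8))
  expect_equal(cal$cutoff, 1e-8)
  expect_equal(nrow(cal$table), 3)
  expect_error(calibrate_cutoff(noise, "a", "b", candidate_cutoffs = numeric(0)),
               "empty candidate")
})

test_that("calibration is invariant to duplicating the hit list", {
  hits <- simulate_fimo_hits(n_genes_per_species = 80, n_targets = 15, seed = 42)
  targets <- sprintf("species_1_g%03d", 1:15)
  background <- sprintf("species_1_g%03d", 16:80)
  sp1 <- hits[hits$species == "species_1", ]
  c1 <- calibrate_cutoff(sp1, targets, background)
  c2 <- calibrate_cutoff(rbind(sp1, sp1), targets, background)
  expect_equal(c1$cutoff, c2$cutoff)
  expect_equal(c1$table, c2$table)
})

test_that("gene-level enrichment reproduces the known target/background fractions", {
  # 29 of 49 target genes vs 328 of 5073 background genes with a hit
  res <- enrichment_from_counts(29, 49, 328, 5073)
  expect_equal(res$target_fraction, 59.2)
  expect_equal(res$background_fraction, 6.5)
  expect_equal(signif(res$p, 3), 7.47e-22)
  # identical fractions carry no signal
  expect_equal(enrichment_from_counts(5, 10, 50, 100)$p, 1.0)
})

test_that("gene-level enrichment counts genes with hits inside the window", {
  hits <- data.frame(motif_id = "FLEX",
                     sequence_name = c("t1", "t1", "t2", "b1"),
                     start = c(100L, 1500L, 900L, 200L),
                     stop = c(110L, 1510L, 910L, 210L),
                     strand = "+", score = 10, p_value = 1e-8,
                     gene_id = c("t1", "t1", "t2", "b1"),
                     species = "sp", stringsAsFactors = FALSE)
  res <- gene_level_enrichment(classify_hits(hits, 3e-6),
                               target_genes = c("t1", "t2", "t3"),
                               background_genes = c("b1", "b2"), window = 1000)
  expect_equal(res$target_with, 2)    # t1 (in-window hit), t2; t3 has none
  expect_equal(res$background_with, 1)
  # a stricter cutoff can only lose genes
  res2 <- gene_level_enrichment(classify_hits(hits, 1e-9),
                                c("t1", "t2", "t3"), c("b1", "b2"))
  expect_lte(res2$target_with, res$target_with)
  expect_error(gene_level_enrichment(hits, c("a", "b"), c("b", "c")),
               "disjoint")
})

test_that("permuted gene labels give approximately uniform enrichment p-values", {
  set.seed(61)
  all_genes <- sprintf("g%03d", 1:60)
  hits <- data.frame(motif_id = "FLEX", sequence_name = all_genes[1:20],
                     start = 100L, stop = 110L, strand = "+", score = 10,
                     p_value = 1e-8, gene_id = all_genes[1:20],
                     species = "sp", stringsAsFactors = FALSE)
  ps <- replicate(200, {
    idx <- sample(60, 10)
    gene_level_enrichment(hits, all_genes[idx], all_genes[-idx])$p
  })
  expect_lt(mean(ps < 0.05), 0.08)
})

test_that("binary feature association builds the expected table", {
  # 20 motif-positive genes, 17 with short transcripts; 28 motif-negative,
  # 14 with short transcripts
  gt <- data.frame(
    gene_id = sprintf("g%02d", 1:48),
    has_flex = rep(c(1, 0), c(20, 28)),
    short = c(rep(c(1, 0), c(17, 3)), rep(c(1, 0), c(14, 14))))
  res <- feature_association(gt, "has_flex", "short")
  expect_equal(unname(res$table), matrix(c(17, 3, 14, 14), 2, byrow = TRUE))
  expect_equal(signif(res$p, 2), 0.016)
  # degenerate all-positive feature
  gt$always <- 1
  expect_equal(feature_association(gt, "always", "short")$p, 1.0)
})

test_that("rank-extremes association reproduces the top/bottom contrast", {
  # 31 ranked genes; 9 of the top 10 and 2 of the bottom 10 carry the motif
  set.seed(62)
  gt <- data.frame(
    gene_id = sprintf("g%02d", 1:31),
    reads = 1000 - seq_len(31) * 10,
    flex = 0L)
  gt$flex[1:9] <- 1L     # 9 of top 10
  gt$flex[c(12, 15:20)] <- 1L  # mid-ranked carriers, not counted
  gt$flex[25] <- 1L; gt$flex[30] <- 1L  # 2 of bottom 10
  res <- rank_extremes_association(gt, "reads", "flex", 10, 10)
  expect_equal(unname(res$table), matrix(c(9, 2, 1, 8), 2, byrow = TRUE))
  expect_equal(signif(res$p, 2), 0.0055)
  expect_error(rank_extremes_association(gt, "reads", "flex", 20, 20),
               "exceeds")
})

test_that("rank-extremes ties are broken by gene id and zeros are excluded", {
  gt <- data.frame(gene_id = c("b", "a", "c", "d", "e"),
                   reads = c(5, 5, 3, 1, 0),
                   flex = c(1, 0, 1, 0, 1))
  res <- rank_extremes_association(gt, "reads", "flex", 2, 2)
  expect_identical(res$top, c("a", "b"))       # tie at 5 broken by id
  expect_identical(res$bottom, c("c", "d"))    # e excluded: no reads
  # degenerate: feature identical in both extremes
  gt2 <- data.frame(gene_id = letters[1:6], reads = 6:1, flex = 1)
  expect_equal(rank_extremes_association(gt2, "reads", "flex", 3, 3)$p, 1.0)
})

test_that("rank-extremes association agrees with the hypergeometric oracle", {
  set.seed(63)
  for (i in 1:30) {
    n <- 25
    gt <- data.frame(gene_id = sprintf("g%02d", 1:n),
                     reads = sample(1:1000, n),
                     flex = rbinom(n, 1, 0.5))
    k <- sample(3:10, 1)
    res <- rank_extremes_association(gt, "reads", "flex", k, k)
    tb <- res$table
    expect_equal(res$p, oracle_fisher(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 tolerance = 1e-10)
  }
})

test_that("FIMO tables round-trip through read_fimo_hits", {
  hits <- simulate_fimo_hits(n_genes_per_species = 20, n_species = 2, seed = 77)
  f <- tempfile(fileext = ".tsv")
  out <- hits
  names(out)[names(out) == "p_value"] <- "p-value"  # FIMO's own header
  write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_fimo_hits(f)
  expect_equal(back$p_value, hits$p_value)
  expect_equal(back$gene_id, hits$gene_id)
  # missing required column is an error
  f2 <- tempfile(fileext = ".tsv")
  write.table(out[setdiff(names(out), "start")], f2, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_fimo_hits(f2), "missing columns")
})
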