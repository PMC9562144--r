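# Reproducible generators for every input the pipeline consumes: octad
# dissection tables, gene/expression tables, and FIMO-style motif-hit
# tables. All generators are deterministic given their seed and leave the
# caller's RNG state untouched.

#' Specification of a simulated octad dissection experiment
#'
#' @param cross_type `"heterozygous"`, `"homozygous_deletion"` or
#'   `"homozygous_wildtype"`.
#' @param v Background per-spore viability probability.
#' @param k Kill probability for spores lacking the driver (ignored for
#'   homozygous crosses, where no killing occurs).
#' @param killing_unit `"spore"` or `"meiotic_product"` (see
#'   [drive_params()]).
#' @param n_octads Number of asci dissected.
#' @param incomplete_rate Probability that a dissected ascus yields fewer
#'   than eight spores (the number dissected is then uniform on 4–7).
#' @param aberrant_rate Probability that a heterozygous octad has a
#'   non-4:4 genotype constitution (5:3 or 6:2 with equal probability and
#'   random majority allele), standing in for gene-conversion events; such
#'   octads exist only to exercise the aberrant filter.
#' @param cross_id,gene Identifiers written into the dataset.
#' @param seed Integer seed (required).
#' @return An `octad_sim_spec` object.
#' @export
octad_sim_spec <- function(cross_type = "heterozygous", v = 0.95, k = 0,
                           killing_unit = c("spore", "meiotic_product"),
                           n_octads = 20, incomplete_rate = 0,
                           aberrant_rate = 0, cross_id = "sim_cross",
                           gene = "sim_gene", seed) {
  killing_unit <- match.arg(killing_unit)
  stopifnot(cross_type %in% .cross_types,
            v >= 0, v <= 1, k >= 0, k <= 1,
            incomplete_rate >= 0, incomplete_rate <= 1,
            aberrant_rate >= 0, aberrant_rate <= 1,
            n_octads >= 1)
  if (missing(seed)) stop("an explicit seed is required")
  structure(list(cross_type = cross_type, v = v, k = k,
                 killing_unit = killing_unit, n_octads = n_octads,
                 incomplete_rate = incomplete_rate,
                 aberrant_rate = aberrant_rate,
                 cross_id = cross_id, gene = gene, seed = seed),
            class = "octad_sim_spec")
}

#' Simulate an octad dissection dataset
#'
#' Forward simulation of the poison/antidote killing model over dissected
#' octads. Heterozygous octads are built from two non-carrier (R) spore
#' pairs and two carrier (S) spore pairs — spores of the same meiotic
#' product share a genotype — laid out in fixed pair blocks (A,B), (C,D),
#' (E,F), (G,H); spore labels carry no positional meaning for any
#' downstream statistic. Killing removes non-carrier spores with
#' probability `k` (per spore, or jointly per pair under
#' `"meiotic_product"`); every surviving spore then germinates with the
#' background probability `v`. Aberrant octads (rate `aberrant_rate`)
#' receive a 5:3 or 6:2 genotype constitution with per-spore killing.
#' Homozygous octads have a uniform genotype and only background death.
#' Inviable spores are reported ungenotyped (U), as replica plating would
#' leave them.
#'
#' @param spec An [octad_sim_spec()].
#' @return A validated `cross_dataset`.
#' @export
simulate_octads <- function(spec) {
  stopifnot(inherits(spec, "octad_sim_spec"))
  withr_seed(spec$seed, .simulate_octads_impl(spec))
}

.simulate_octads_impl <- function(spec) {
  n <- spec$n_octads
  v <- spec$v
  k <- spec$k
  het <- spec$cross_type == "heterozygous"

  # genotype layout, one row per octad, 8 columns
  geno <- matrix(if (het) rep(c("R", "R", "R", "R", "S", "S", "S", "S"), each = n)
                 else if (spec$cross_type == "homozygous_deletion") "R" else "S",
                 nrow = n, ncol = 8)
  aberrant <- if (het && spec$aberrant_rate > 0)
    stats::runif(n) < spec$aberrant_rate else rep(FALSE, n)
  for (i in which(aberrant)) {
    n_major <- sample(c(5L, 6L), 1)
    major <- sample(c("R", "S"), 1)
    geno[i, ] <- c(rep(major, n_major),
                   rep(setdiff(c("R", "S"), major), 8 - n_major))
  }

  # killing of non-carrier spores, then background death
  is_R <- geno == "R"
  killed <- matrix(FALSE, n, 8)
  if (het && k > 0) {
    if (spec$killing_unit == "meiotic_product") {
      reg <- !aberrant
      for (pair in list(1:2, 3:4)) {  # the two R pair blocks in regular octads
        hit <- reg & stats::runif(n) < k
        killed[hit, pair] <- TRUE
      }
      # aberrant octads have no pair structure: per-spore killing
      killed[aberrant & is_R] <- stats::runif(sum(aberrant & is_R)) < k
    } else {
      killed[is_R] <- stats::runif(sum(is_R)) < k
    }
  }
  viable <- !killed & matrix(stats::runif(n * 8) < v, n, 8)

  # incomplete dissections: keep only m ~ Uniform{4..7} random spores
  keep <- matrix(TRUE, n, 8)
  if (spec$incomplete_rate > 0) {
    for (i in which(stats::runif(n) < spec$incomplete_rate)) {
      m <- sample(4:7, 1)
      keep[i, sample.int(8, 8 - m)] <- FALSE
    }
  }

  idx <- which(t(keep))  # row-major over octads
  octad_of <- rep(seq_len(n), each = 8)[idx]
  spore_of <- rep(1:8, n)[idx]
  viable_v <- t(viable)[idx]
  geno_v <- ifelse(viable_v, t(geno)[idx], "U")

  spores <- data.frame(
    cross_id = spec$cross_id,
    ascus_id = sprintf("octad_%04d", octad_of),
    spore_index = .spore_labels[spore_of],
    viable = viable_v,
    genotype = geno_v,
    stringsAsFactors = FALSE
  )
  cross_dataset(cross_info(spec$cross_id, spec$gene, spec$cross_type), spores)
}

#' Specification of a simulated gene/expression table
#'
#' Emulates a table of candidate genes in which carrying a confident
#' regulatory-motif (FLEX) hit in intron 1 raises both the probability of
#' detecting a short (poison-isoform) transcript and its expression
#' level. A latent log-expression level is normal with mean shifted up by
#' `flex_shift` for motif-positive genes; detection follows a logistic
#' link on that latent level and detected genes receive a negative
#' binomial read count.
#'
#' @param n_genes Number of genes (default 48).
#' @param flex_prevalence Probability a gene carries a confident motif hit
#'   (default 20/48).
#' @param flex_shift Upward shift of the latent expression level for
#'   motif-positive genes (default 1.7, giving roughly 85% detection for
#'   motif-positive vs 50% for motif-negative genes).
#' @param detect_intercept Logistic intercept of short-transcript
#'   detection at latent level 0 (default 0).
#' @param mu0 Baseline mean read count of a detected short transcript
#'   (default 20).
#' @param dispersion Negative-binomial size parameter (default 1.0,
#'   mimicking noisy long-read counts).
#' @param seed Integer seed (required).
#' @return A `gene_table_sim_spec` object.
#' @export
gene_table_sim_spec <- function(n_genes = 48, flex_prevalence = 20 / 48,
                                flex_shift = 1.7, detect_intercept = 0,
                                mu0 = 20, dispersion = 1.0, seed) {
  stopifnot(n_genes >= 1, flex_prevalence >= 0, flex_prevalence <= 1,
            dispersion > 0, mu0 > 0)
  if (missing(seed)) stop("an explicit seed is required")
  structure(list(n_genes = n_genes, flex_prevalence = flex_prevalence,
                 flex_shift = flex_shift, detect_intercept = detect_intercept,
                 mu0 = mu0, dispersion = dispersion, seed = seed),
            class = "gene_table_sim_spec")
}

#' Simulate a gene/expression table
#'
#' @param spec A [gene_table_sim_spec()].
#' @return A data.frame with columns `gene_id`, `has_confident_flex_hit`
#'   (0/1), `short_transcript_detected` (0/1) and `short_read_count`
#'   (positive iff detected).
#' @export
simulate_gene_table <- function(spec) {
  stopifnot(inherits(spec, "gene_table_sim_spec"))
  withr_seed(spec$seed, {
    n <- spec$n_genes
    flex <- stats::rbinom(n, 1, spec$flex_prevalence)
    latent <- stats::rnorm(n, mean = spec$flex_shift * flex, sd = 1)
    detected <- stats::rbinom(n, 1, stats::plogis(spec$detect_intercept + latent))
    count <- integer(n)
    hit <- detected == 1
    count[hit] <- 1L + stats::rnbinom(sum(hit), size = spec$dispersion,
                                      mu = spec$mu0 * exp(latent[hit] / 2))
    data.frame(gene_id = sprintf("gene_%03d", seq_len(n)),
               has_confident_flex_hit = flex,
               short_transcript_detected = detected,
               short_read_count = count,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a FIMO-style motif-hit table
#'
#' Generates per-species hit tables as a two-component mixture: signal
#' hits concentrated in a target gene set, with small scan p-values and
#' positions inside the upstream window, plus noise hits scattered over
#' all genes with larger p-values. p-values are drawn log-uniformly from
#' the given ranges (log10 scale).
#'
#' @param n_genes_per_species Genes per species (default 100).
#' @param n_species Number of species (default 4).
#' @param n_targets Target genes per species, taken as the first genes of
#'   each species (default 10).
#' @param signal_rate Probability a target gene receives a signal hit
#'   (default 0.9).
#' @param signal_logp Range of log10 p-values for signal hits (default
#'   c(-9, -6.5)).
#' @param noise_mean Mean number of noise hits per gene, Poisson
#'   (default 0.5).
#' @param noise_logp Range of log10 p-values for noise hits (default
#'   c(-5.5, -4)).
#' @param window Length of the upstream window; signal hits start inside
#'   it (default 1000).
#' @param seq_length Length of each scanned sequence; noise hits start
#'   anywhere on it (default 2000).
#' @param seed Integer seed (required).
#' @return A data.frame in FIMO dialect (`motif_id`, `sequence_name`,
#'   `start`, `stop`, `strand`, `score`, `p_value`, `matched_sequence`)
#'   plus `species`, `gene_id` and `is_target` columns.
#' @export
simulate_fimo_hits <- function(n_genes_per_species = 100, n_species = 4,
                               n_targets = 10, signal_rate = 0.9,
                               signal_logp = c(-9, -6.5), noise_mean = 0.5,
                               noise_logp = c(-5.5, -4), window = 1000,
                               seq_length = 2000, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(n_targets <= n_genes_per_species)
  withr_seed(seed, {
    out <- list()
    for (sp in seq_len(n_species)) {
      species <- sprintf("species_%d", sp)
      genes <- sprintf("%s_g%03d", species, seq_len(n_genes_per_species))
      target <- seq_len(n_targets)
      # signal component
      sig_genes <- target[stats::runif(n_targets) < signal_rate]
      sig <- if (length(sig_genes)) data.frame(
        species = species, gene_id = genes[sig_genes],
        is_target = TRUE,
        start = sample.int(window - 10L, length(sig_genes), replace = TRUE),
        log10p = stats::runif(length(sig_genes), signal_logp[1], signal_logp[2]),
        stringsAsFactors = FALSE)
      # noise component
      n_noise <- stats::rpois(n_genes_per_species, noise_mean)
      noise_gene <- rep(seq_len(n_genes_per_species), n_noise)
      noise <- if (length(noise_gene)) data.frame(
        species = species, gene_id = genes[noise_gene],
        is_target = noise_gene <= n_targets,
        start = sample.int(seq_length - 10L, length(noise_gene), replace = TRUE),
        log10p = stats::runif(length(noise_gene), noise_logp[1], noise_logp[2]),
        stringsAsFactors = FALSE)
      out[[sp]] <- rbind(sig, noise)
    }
    hits <- do.call(rbind, out)
    data.frame(
      motif_id = "FLEX",
      sequence_name = hits$gene_id,
      start = hits$start,
      stop = hits$start + 10L,
      strand = ifelse(stats::runif(nrow(hits)) < 0.5, "+", "-"),
      score = round(-10 * hits$log10p, 3),
      p_value = 10^hits$log10p,
      matched_sequence = "GTAAACAAACA",
      species = hits$species,
      gene_id = hits$gene_id,
      is_target = hits$is_target,
      stringsAsFactors = FALSE
    )
  })
}
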