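# Independent brute-force oracles for the exact tests, and small dataset
# builders shared across test files.

# two-sided Fisher p by direct enumeration of all 2x2 tables with the
# observed margins, table probabilities from the factorial formula
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; N <- sum(a, b, c, d)
  tab_prob <- function(x) {
    # table (x, r1-x; c1-x, r2-c1+x)
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
          lfactorial(N) - lfactorial(x) - lfactorial(r1 - x) -
          lfactorial(c1 - x) - lfactorial(r2 - c1 + x))
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, tab_prob, numeric(1))
  obs <- tab_prob(a)
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# two-sided binomial p by direct enumeration with choose()
oracle_binom <- function(x, n, p0) {
  probs <- choose(n, 0:n) * p0^(0:n) * (1 - p0)^(n - (0:n))
  obs <- probs[x + 1]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# build a heterozygous cross_dataset from per-octad viable genotype
# strings, e.g. "RRSS" means 2 viable R, 2 viable S, 4 dead spores
make_het <- function(viable_genotypes, cross_id = "het", n_spores = 8) {
  rows <- lapply(seq_along(viable_genotypes), function(i) {
    g <- strsplit(viable_genotypes[i], "")[[1]]
    stopifnot(length(g) <= n_spores)
    geno <- c(g, rep("U", n_spores - length(g)))
    data.frame(ascus_id = sprintf("o%03d", i),
               spore_index = LETTERS[1:n_spores],
               viable = c(rep(TRUE, length(g)), rep(FALSE, n_spores - length(g))),
               genotype = geno, stringsAsFactors = FALSE)
  })
  cross_dataset(cross_info(cross_id, "geneX", "heterozygous"),
                do.call(rbind, rows))
}

make_control <- function(n_octads = 10, n_dead = 0, cross_id = "ctrl") {
  rows <- lapply(seq_len(n_octads), function(i) {
    dead <- rep(FALSE, 8)
    if (n_dead > 0 && i <= n_dead) dead[1] <- TRUE
    data.frame(ascus_id = sprintf("c%03d", i), spore_index = LETTERS[1:8],
               viable = !dead, genotype = ifelse(dead, "U", "S"),
               stringsAsFactors = FALSE)
  })
  cross_dataset(cross_info(cross_id, "none", "homozygous_wildtype"),
                do.call(rbind, rows))
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "octadrive", mustWork = TRUE)
}
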