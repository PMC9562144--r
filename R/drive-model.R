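# Generative probability model of poison/antidote spore killing in
# octads, with likelihood, maximum-likelihood estimation, bootstrap
# confidence intervals, and Monte-Carlo power analysis.
#
# Model: a heterozygous meiosis yields exactly two driver-carrying (S)
# and two non-carrying (R) meiotic products; the post-meiotic mitosis
# duplicates each into a spore pair, giving 4 S and 4 R spores. All
# spores are exposed to the poison; spores inheriting the driver are
# rescued by the antidote. Two parameters:
#   v  background per-spore viability probability
#   k  probability that a non-carrier spore (or meiotic product) is killed
# Carrier (S) spores suffer only background death (the antidote is
# treated as fully protective). killing_unit = "spore" kills each R spore
# independently; killing_unit = "meiotic_product" kills both spores of an
# R pair jointly (sister spores are genetically identical and may be
# jointly exposed), then survivors die independently at the background
# rate.

#' Parameters of the poison/antidote spore-killing model
#'
#' @param v Background per-spore viability probability in `[0, 1]`.
#' @param k Kill probability applied to spores lacking the driver, in
#'   `[0, 1]`.
#' @param killing_unit `"spore"` (independent killing, default) or
#'   `"meiotic_product"` (both spores of a non-carrier pair killed jointly).
#' @return A `drive_params` object.
#' @export
drive_params <- function(v, k, killing_unit = c("spore", "meiotic_product")) {
  killing_unit <- match.arg(killing_unit)
  stopifnot(is.numeric(v), length(v) == 1, v >= 0, v <= 1,
            is.numeric(k), length(k) == 1, k >= 0, k <= 1)
  structure(list(v = v, k = k, killing_unit = killing_unit),
            class = "drive_params")
}

# distribution of viable spores contributed by one non-carrier pair
# under joint (meiotic_product) killing: 0 with prob k, else Binomial(2, v)
.pair_pmf_R <- function(v, k) {
  p <- (1 - k) * stats::dbinom(0:2, 2, v)
  p[1] <- p[1] + k
  p
}

#' Joint distribution of octad types under the killing model
#'
#' Probability of observing `r` viable non-carrier (R) and `s` viable
#' carrier (S) spores in a retained heterozygous octad, for all
#' `(r, s)` in `{0..4} x {0..4}`.
#'
#' Under `killing_unit = "spore"`, `r ~ Binomial(4, v(1-k))` and
#' `s ~ Binomial(4, v)`, independent. Under `"meiotic_product"`, each R
#' pair is jointly killed with probability `k` and survivors die
#' independently; the pmf of `r` is the convolution of the two pair
#' distributions. The marginal mean of `r` is `4 v (1-k)` for both units,
#' but the variance differs for `0 < k < 1`.
#'
#' @param params A [drive_params()] object.
#' @return A 5x5 matrix of probabilities (rows `r` = 0–4, columns `s` =
#'   0–4) summing to 1.
#' @export
octad_type_pmf <- function(params) {
  stopifnot(inherits(params, "drive_params"))
  v <- params$v; k <- params$k
  s_pmf <- stats::dbinom(0:4, 4, v)
  if (params$killing_unit == "spore") {
    r_pmf <- stats::dbinom(0:4, 4, v * (1 - k))
  } else {
    pair <- .pair_pmf_R(v, k)
    r_pmf <- as.vector(stats::convolve(pair, rev(pair), type = "open"))
    r_pmf[r_pmf < 0] <- 0  # guard against convolve round-off
  }
  pmf <- outer(r_pmf, s_pmf)
  dimnames(pmf) <- list(r = 0:4, s = 0:4)
  pmf
}

#' Expected transmission distortion ratio under the killing model
#'
#' The expected proportion of driver-carrying spores among viable spores
#' is `1 / (2 - k)`, independent of the background viability `v` and of
#' the killing unit: 0.5 with no killing, 1 with complete killing.
#'
#' @param params A [drive_params()] object (or a kill probability `k`).
#' @return A probability in `[0.5, 1]`.
#' @export
expected_tdr <- function(params) {
  k <- if (inherits(params, "drive_params")) params$k else params
  stopifnot(is.numeric(k), all(k >= 0), all(k <= 1))
  1 / (2 - k)
}

#' Log-likelihood of octad-type counts under the killing model
#'
#' @param counts An `octad_type_counts` object.
#' @param params A [drive_params()] object.
#' @return The log-likelihood; `-Inf` if a class with positive count has
#'   zero probability.
#' @export
octad_loglik <- function(counts, params) {
  stopifnot(inherits(counts, "octad_type_counts"))
  pmf <- octad_type_pmf(params)
  obs <- counts$counts > 0
  if (any(obs & pmf == 0)) return(-Inf)
  sum(counts$counts[obs] * log(pmf[obs]))
}

#' Maximum-likelihood estimation of the killing-model parameters
#'
#' For `killing_unit = "spore"` the MLE is closed form: `v` is estimated
#' from the carrier spores (`mean(s) / 4`) and `k` from the deficit of
#' non-carrier spores (`1 - mean(r) / (4 v)`), both clipped to `[0, 1]`.
#' For `"meiotic_product"` the likelihood is maximized numerically over
#' the unit square (21x21 grid initialization, then local refinement to a
#' log-likelihood tolerance of 1e-9; among grid optima tied within that
#' tolerance the one with smaller `k` is taken). Confidence intervals are
#' percentile bootstrap over octads, which remains usable at boundary
#' estimates `k = 0` or `k = 1`.
#'
#' @param counts An `octad_type_counts` object with at least one octad.
#' @param killing_unit `"spore"` or `"meiotic_product"`.
#' @param bootstrap Number of bootstrap replicates for the 95% confidence
#'   intervals (default 1000; 0 skips the bootstrap).
#' @param seed Integer seed for the bootstrap resampling (required when
#'   `bootstrap > 0`).
#' @return An `mle_fit` object with `v_hat`, `k_hat`, `loglik`, `ci_v`,
#'   `ci_k`, `n_octads`, `method` and `killing_unit`.
#' @export
fit_mle <- function(counts, killing_unit = c("spore", "meiotic_product"),
                    bootstrap = 1000, seed = NULL) {
  killing_unit <- match.arg(killing_unit)
  stopifnot(inherits(counts, "octad_type_counts"))
  if (counts$n_octads < 1) stop("need at least one octad")
  if (bootstrap > 0 && is.null(seed))
    stop("an explicit seed is required for the bootstrap")

  est <- .fit_point(counts, killing_unit)
  ci_v <- ci_k <- c(NA_real_, NA_real_)
  if (bootstrap > 0) {
    # resample octads (not spores): the octad is the sampling unit
    idx <- which(counts$counts > 0, arr.ind = TRUE)
    octs <- data.frame(r = rep(idx[, 1] - 1L, counts$counts[idx]),
                       s = rep(idx[, 2] - 1L, counts$counts[idx]))
    boots <- withr_seed(seed, {
      vapply(seq_len(bootstrap), function(i) {
        take <- sample.int(nrow(octs), replace = TRUE)
        b <- .fit_point(octad_type_counts(octs$r[take], octs$s[take],
                                          counts$cross_id), killing_unit)
        c(b$v, b$k)
      }, numeric(2))
    })
    ci_v <- unname(stats::quantile(boots[1, ], c(0.025, 0.975)))
    ci_k <- unname(stats::quantile(boots[2, ], c(0.025, 0.975)))
  }
  structure(list(v_hat = est$v, k_hat = est$k,
                 loglik = octad_loglik(counts, drive_params(est$v, est$k, killing_unit)),
                 ci_v = ci_v, ci_k = ci_k,
                 n_octads = counts$n_octads,
                 method = if (killing_unit == "spore") "closed_form" else "numerical",
                 killing_unit = killing_unit,
                 n_bootstrap = bootstrap, seed = seed),
            class = "mle_fit")
}

.fit_point <- function(counts, killing_unit) {
  m <- counts$counts
  n <- sum(m)
  mean_r <- sum((0:4) * rowSums(m)) / n
  mean_s <- sum((0:4) * colSums(m)) / n
  if (killing_unit == "spore") {
    v <- min(1, max(0, mean_s / 4))
    if (v == 0) {
      if (mean_r > 0)
        stop("inconsistent data: estimated background viability 0 with viable R spores")
      return(list(v = 0, k = 0))
    }
    k <- min(1, max(0, 1 - mean_r / (4 * v)))
    return(list(v = v, k = k))
  }
  # meiotic_product: grid then local refinement
  grid <- seq(0, 1, length.out = 21)
  ll <- outer(grid, grid, Vectorize(function(v, k)
    octad_loglik(counts, drive_params(v, k, "meiotic_product"))))
  best <- max(ll)
  tied <- which(ll >= best - 1e-9, arr.ind = TRUE)
  # tie-break toward the smaller k
  pick <- tied[order(grid[tied[, 2]], grid[tied[, 1]])[1], ]
  start <- c(grid[pick[1]], grid[pick[2]])
  neg <- function(par) {
    val <- octad_loglik(counts, drive_params(par[1], par[2], "meiotic_product"))
    if (!is.finite(val)) 1e12 else -val
  }
  opt <- stats::optim(start, neg, method = "L-BFGS-B",
                      lower = c(1e-9, 0), upper = c(1, 1),
                      control = list(factr = 1))
  list(v = opt$par[1], k = opt$par[2])
}

#' @export
print.mle_fit <- function(x, ...) {
  cat(sprintf("<mle_fit> (%s, %s) on %d octad(s)\n",
              x$killing_unit, x$method, x$n_octads))
  cat(sprintf("  v_hat = %.4f [%.4f, %.4f]\n", x$v_hat, x$ci_v[1], x$ci_v[2]))
  cat(sprintf("  k_hat = %.4f [%.4f, %.4f]\n", x$k_hat, x$ci_k[1], x$ci_k[2]))
  cat(sprintf("  loglik = %.4f\n", x$loglik))
  invisible(x)
}

#' Monte-Carlo power of the active-driver call
#'
#' Simulates dissection experiments of the given sizes under the killing
#' model (heterozygous cross) and pure background death (wild-type
#' control), runs the full filter/report/classification pipeline on each
#' replicate, and returns the fraction of replicates classified
#' `active_driver`. With `k = 0` this estimates the type-I error rate of
#' the combined decision rule.
#'
#' @param params [drive_params()] for the heterozygous cross.
#' @param n_octads Octads dissected in the cross.
#' @param control_v Background viability of the wild-type control cross.
#' @param n_control Octads dissected in the control.
#' @param reps Number of Monte-Carlo replicates (>= 100).
#' @param seed Integer seed.
#' @param alpha,min_reduction_pp Passed to [drive_report()].
#' @return The estimated power, a probability.
#' @export
power_analysis <- function(params, n_octads, control_v = params$v,
                           n_control = n_octads, reps = 200, seed,
                           alpha = 0.05, min_reduction_pp = 5) {
  stopifnot(inherits(params, "drive_params"), reps >= 100)
  if (missing(seed)) stop("an explicit seed is required")
  hits <- withr_seed(seed, {
    vapply(seq_len(reps), function(i) {
      cross <- simulate_octads(octad_sim_spec(
        cross_type = "heterozygous", v = params$v, k = params$k,
        killing_unit = params$killing_unit, n_octads = n_octads,
        seed = sample.int(.Machine$integer.max, 1)))
      ctrl <- simulate_octads(octad_sim_spec(
        cross_type = "homozygous_wildtype", v = control_v, k = 0,
        n_octads = n_control, cross_id = "control",
        seed = sample.int(.Machine$integer.max, 1)))
      rep <- tryCatch(
        drive_report(filter_octads(cross), filter_octads(ctrl),
                     alpha = alpha, min_reduction_pp = min_reduction_pp),
        error = function(e) NULL)
      !is.null(rep) && rep$status == "active_driver"
    }, logical(1))
  })
  mean(hits)
}

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
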