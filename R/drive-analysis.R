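# Drive-detection statistics: spore viability comparison, allele
# transmission tests, mirror octad-type ratio tests, and the decision
# rules that call a gene an active or weak meiotic driver.

.viable_counts <- function(dataset) {
  sp <- dataset$spores
  c(viable = sum(sp$viable), dissected = nrow(sp))
}

.genotype_counts <- function(dataset) {
  sp <- dataset$spores
  c(R = sum(sp$viable & sp$genotype == "R"),
    S = sum(sp$viable & sp$genotype == "S"))
}

#' Compare pooled spore viability between a cross and its control
#'
#' Viability is pooled over spores of the retained octads (viable spores /
#' dissected spores), and the difference is tested with a two-sided
#' Fisher's exact test on the (viable, inviable) x (cross, control) table.
#'
#' @param cross,control Filtered `cross_dataset` objects; `control` is the
#'   user-designated wild-type control cross.
#' @return A list with `viability` and `control_viability` (each
#'   viable/dissected counts and the fraction), `reduction_pp` (control
#'   minus cross, in percentage points) and `p_viability`.
#' @export
viability_comparison <- function(cross, control) {
  stopifnot(inherits(cross, "cross_dataset"), inherits(control, "cross_dataset"))
  if (is.null(cross$filter_report) || is.null(control$filter_report))
    stop("both datasets must be filtered with filter_octads()")
  vc <- .viable_counts(cross)
  vk <- .viable_counts(control)
  if (vc["dissected"] == 0 || vk["dissected"] == 0)
    stop("empty retained octad set in cross or control")
  frac_cross <- vc["viable"] / vc["dissected"]
  frac_ctrl <- vk["viable"] / vk["dissected"]
  p <- fisher_exact_two_sided(vc["viable"], vc["dissected"] - vc["viable"],
                              vk["viable"], vk["dissected"] - vk["viable"])
  list(
    viability = list(viable = unname(vc["viable"]),
                     dissected = unname(vc["dissected"]),
                     fraction = unname(frac_cross)),
    control_viability = list(viable = unname(vk["viable"]),
                             dissected = unname(vk["dissected"]),
                             fraction = unname(frac_ctrl)),
    reduction_pp = unname(100 * (frac_ctrl - frac_cross)),
    p_viability = p
  )
}

#' Test allele transmission among viable spores of a heterozygous cross
#'
#' Under Mendelian segregation the wild-type (S) and deletion (R) alleles
#' are equally represented among viable spores; drive of the wild-type
#' allele shows up as an excess of S. The exact binomial test compares the
#' S count against 0.5.
#'
#' @param dataset A filtered heterozygous `cross_dataset`.
#' @return List with `n_S`, `n_R`, `n` (= n_S + n_R) and the two-sided
#'   `p` from [exact_binomial_two_sided()].
#' @export
transmission_test <- function(dataset) {
  stopifnot(inherits(dataset, "cross_dataset"))
  if (dataset$info$cross_type != "heterozygous")
    stop("transmission test applies to heterozygous crosses only")
  g <- .genotype_counts(dataset)
  n <- sum(g)
  if (n == 0) stop("no viable genotyped spores")
  list(n_S = unname(g["S"]), n_R = unname(g["R"]), n = n,
       p = exact_binomial_two_sided(g["S"], n, 0.5))
}

#' Transmission distortion ratio
#'
#' The proportion of wild-type-allele (S) spores among all viable
#' genotyped spores of a heterozygous cross: 0.5 under Mendelian
#' segregation, above 0.5 when the wtf+ allele drives.
#'
#' @param dataset A filtered heterozygous `cross_dataset`.
#' @return A number in `[0, 1]`.
#' @export
transmission_distortion_ratio <- function(dataset) {
  g <- .genotype_counts(dataset)
  if (sum(g) == 0) stop("no viable genotyped spores")
  unname(g["S"] / sum(g))
}

# the four mirror octad-type pairs tested against 1:1
.mirror_pairs <- list(c(4L, 3L), c(4L, 2L), c(4L, 1L), c(4L, 0L))

#' Mirror octad-type ratio tests
#'
#' Without drive, octad types that mirror each other in R and S (4R3S vs
#' 3R4S, 4R2S vs 2R4S, 4R1S vs 1R4S, 4R0S vs 0R4S) are equally likely, so
#' their counts are tested against a 1:1 ratio with the exact binomial
#' test. A p-value is only reported when a pair has more than five octads
#' in total; below that the test cannot reach the usual significance
#' threshold and the pair is marked gated.
#'
#' @param counts An `octad_type_counts` object.
#' @return A data.frame with one row per mirror pair: `pair` (label),
#'   `n_first` (count of the R-majority type), `n_second` (S-majority),
#'   `total`, `gated` (logical) and `p` (NA when gated).
#' @export
octad_ratio_tests <- function(counts) {
  stopifnot(inherits(counts, "octad_type_counts"))
  m <- counts$counts
  res <- lapply(.mirror_pairs, function(pr) {
    r <- pr[1]; s <- pr[2]
    n_first <- m[r + 1, s + 1]   # rRsS
    n_second <- m[s + 1, r + 1]  # sRrS (mirror)
    total <- n_first + n_second
    gated <- total <= 5
    data.frame(
      pair = sprintf("%dR%dS:%dR%dS", r, s, s, r),
      n_first = n_first, n_second = n_second, total = total,
      gated = gated,
      p = if (gated) NA_real_ else exact_binomial_two_sided(n_first, total, 0.5),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Assemble a full drive report for one heterozygous cross
#'
#' Runs the viability comparison against the control, the transmission
#' test, the transmission distortion ratio and the mirror-pair ratio
#' tests, then applies [classify_driver()].
#'
#' @param cross A filtered heterozygous `cross_dataset`.
#' @param control A filtered wild-type control `cross_dataset`.
#' @param alpha Significance level (default 0.05).
#' @param min_reduction_pp Minimum viability reduction, in percentage
#'   points, required to call an active driver (default 5).
#' @param allow_ungenotyped Passed to [tabulate_types()].
#' @return A `drive_report` object.
#' @export
drive_report <- function(cross, control, alpha = 0.05, min_reduction_pp = 5,
                         allow_ungenotyped = FALSE) {
  viab <- viability_comparison(cross, control)
  trans <- transmission_test(cross)
  counts <- tabulate_types(cross, allow_ungenotyped = allow_ungenotyped)
  ratios <- octad_ratio_tests(counts)
  rep <- structure(list(
    cross_id = cross$info$cross_id,
    gene = cross$info$gene,
    viability = viab$viability,
    control_viability = viab$control_viability,
    reduction_pp = viab$reduction_pp,
    p_viability = viab$p_viability,
    n_viable_R = trans$n_R,
    n_viable_S = trans$n_S,
    tdr = transmission_distortion_ratio(cross),
    p_transmission = trans$p,
    ratio_tests = ratios,
    type_counts = counts,
    status = NA_character_
  ), class = "drive_report")
  rep$status <- classify_driver(rep, alpha = alpha,
                                min_reduction_pp = min_reduction_pp)
  rep
}

#' Classify a cross as an active driver, weak driver, or no drive
#'
#' Decision rules: `active_driver` requires a viability reduction greater
#' than `min_reduction_pp` percentage points with Fisher p below `alpha`,
#' a transmission-test p below `alpha`, and a transmission distortion
#' ratio above 0.5 (so drive of the deletion allele is never labelled a
#' wtf driver). A cross that fails those gates but has at least one
#' non-gated mirror-pair test with p below `alpha` and the bias favouring
#' the wild-type (S) side is a `weak_driver`. Anything else is `no_drive`.
#'
#' @param report A `drive_report` (status field may be unset).
#' @param alpha Significance level.
#' @param min_reduction_pp Viability-reduction threshold in percentage points.
#' @return One of `"active_driver"`, `"weak_driver"`, `"no_drive"`.
#' @export
classify_driver <- function(report, alpha = 0.05, min_reduction_pp = 5) {
  stopifnot(inherits(report, "drive_report"))
  active <- report$reduction_pp > min_reduction_pp &&
    report$p_viability < alpha &&
    report$p_transmission < alpha &&
    report$tdr > 0.5
  if (active) return("active_driver")
  rt <- report$ratio_tests
  hit <- !rt$gated & !is.na(rt$p) & rt$p < alpha & rt$n_second > rt$n_first
  # n_second is the S-majority mirror type, so n_second > n_first means the
  # bias favours the wild-type allele
  if (any(hit)) "weak_driver" else "no_drive"
}

#' @export
print.drive_report <- function(x, ...) {
  cat(sprintf("<drive_report> cross %s (gene %s): %s\n",
              x$cross_id, x$gene, x$status))
  cat(sprintf("  viability %d/%d (%.1f%%) vs control %d/%d (%.1f%%): reduction %.1f pp, p = %.3g\n",
              x$viability$viable, x$viability$dissected, 100 * x$viability$fraction,
              x$control_viability$viable, x$control_viability$dissected,
              100 * x$control_viability$fraction, x$reduction_pp, x$p_viability))
  cat(sprintf("  transmission: %d S vs %d R, TDR = %.3f, p = %.3g\n",
              x$n_viable_S, x$n_viable_R, x$tdr, x$p_transmission))
  rt <- x$ratio_tests
  for (i in seq_len(nrow(rt)))
    cat(sprintf("  %s: %d vs %d, %s\n", rt$pair[i], rt$n_first[i], rt$n_second[i],
                if (rt$gated[i]) "gated (total <= 5)" else sprintf("p = %.3g", rt$p[i])))
  invisible(x)
}

#' Correlation between transmission distortion and poison-isoform expression
#'
#' Spearman rank correlation between per-gene transmission distortion
#' ratios and poison-isoform expression levels (e.g. short-transcript read
#' counts), reported as an exploratory statistic.
#'
#' @param tdr_by_gene Named numeric vector of TDRs.
#' @param expression_by_gene Named numeric vector of expression levels.
#' @return List with `rho`, `p`, and `n` (number of shared genes).
#' @export
tdr_expression_correlation <- function(tdr_by_gene, expression_by_gene) {
  genes <- intersect(names(tdr_by_gene), names(expression_by_gene))
  if (length(genes) < 3)
    stop("need at least 3 genes present in both maps")
  ct <- suppressWarnings(
    stats::cor.test(tdr_by_gene[genes], expression_by_gene[genes],
                    method = "spearman")
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(genes))
}
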