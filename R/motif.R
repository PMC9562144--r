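# Motif-scan cutoff calibration and gene-level enrichment statistics over
# FIMO-style hit tables. The package consumes the tabular output of motif
# scanners (FIMO dialect); it does no motif discovery or scanning itself.

#' Read a FIMO-style motif-hit table
#'
#' Reads a tab-separated hit table with at least the columns `motif_id`,
#' `sequence_name`, `start`, `stop`, `strand`, `score` and a p-value
#' column (`p_value` or FIMO's `p-value`); extra columns are kept.
#' Coordinates are 1-based inclusive. A `species` column, if absent, is
#' filled with `"unknown"`; `gene_id` defaults to `sequence_name`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of motif hits.
#' @export
read_fimo_hits <- function(path) {
  hits <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE, comment.char = "#")
  names(hits)[names(hits) %in% c("p-value", "p.value")] <- "p_value"
  need <- c("motif_id", "sequence_name", "start", "stop", "p_value")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hit table ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  if (!"species" %in% names(hits)) hits$species <- "unknown"
  if (!"gene_id" %in% names(hits)) hits$gene_id <- hits$sequence_name
  if (any(hits$start > hits$stop)) stop("hit with start > stop")
  if (any(hits$p_value <= 0 | hits$p_value > 1)) stop("hit p-values must be in (0, 1]")
  hits
}

#' Partition motif hits into confident and unreliable at a p-value cutoff
#'
#' A hit is confident when its scan p-value is less than or equal to the
#' cutoff (inclusive).
#'
#' @param hits A motif-hit data.frame (see [read_fimo_hits()]).
#' @param cutoff p-value cutoff in (0, 1).
#' @return A `hit_classification` object: the cutoff, the `confident` and
#'   `unreliable` hit subsets, `per_species_confident` counts and
#'   `total_confident`.
#' @export
classify_hits <- function(hits, cutoff) {
  stopifnot(is.data.frame(hits), cutoff > 0, cutoff < 1 || cutoff == 1)
  if (!"species" %in% names(hits)) hits$species <- "unknown"
  conf <- hits$p_value <= cutoff
  per_species <- if (nrow(hits))
    table(factor(hits$species[conf], levels = sort(unique(hits$species))))
  else table(character(0))
  structure(list(cutoff = cutoff,
                 confident = hits[conf, , drop = FALSE],
                 unreliable = hits[!conf, , drop = FALSE],
                 per_species_confident = c(per_species),
                 total_confident = sum(conf)),
            class = "hit_classification")
}

#' @export
print.hit_classification <- function(x, ...) {
  cat(sprintf("<hit_classification> cutoff %.3g: %d confident, %d unreliable\n",
              x$cutoff, x$total_confident, nrow(x$unreliable)))
  print(x$per_species_confident)
  invisible(x)
}

# gene ids of `genes` that have >= 1 hit from `hits` starting inside the
# upstream window
.genes_with_hit <- function(hits, genes, window) {
  inw <- hits$start <= window
  genes %in% hits$gene_id[inw]
}

#' Calibrate the confident-hit p-value cutoff against known target genes
#'
#' For each candidate cutoff, computes the fraction of known target genes
#' with at least one confident hit in the upstream window (sensitivity)
#' and the fraction of background genes with such a hit (false-positive
#' fraction). The chosen cutoff maximizes sensitivity minus
#' false-positive fraction — a concrete reading of maximizing hits in
#' known targets while minimizing hits elsewhere — with ties broken
#' toward the most stringent cutoff. The full per-cutoff table is
#' returned for audit, so other objectives can be applied.
#'
#' @param hits A motif-hit data.frame.
#' @param target_genes,background_genes Character vectors of gene ids
#'   (disjoint, non-empty).
#' @param candidate_cutoffs Candidate p-value cutoffs; default a
#'   decade/half-decade ladder from 1e-4 down to 1e-8.
#' @param window Upstream window length defining membership (default 1000).
#' @return A list with `cutoff` (the chosen one) and `table` (data.frame
#'   with per-cutoff sensitivity, false-positive fraction and objective).
#' @export
calibrate_cutoff <- function(hits, target_genes, background_genes,
                             candidate_cutoffs = c(1e-4, 3e-5, 1e-5, 3e-6,
                                                   1e-6, 3e-7, 1e-7, 3e-8, 1e-8),
                             window = 1000) {
  if (!length(candidate_cutoffs)) stop("empty candidate cutoff list")
  if (!length(target_genes) || !length(background_genes))
    stop("target and background gene sets must be non-empty")
  candidate_cutoffs <- sort(candidate_cutoffs, decreasing = TRUE)
  tab <- do.call(rbind, lapply(candidate_cutoffs, function(co) {
    conf <- hits[hits$p_value <= co, , drop = FALSE]
    sens <- mean(.genes_with_hit(conf, target_genes, window))
    fpf <- mean(.genes_with_hit(conf, background_genes, window))
    data.frame(cutoff = co, sensitivity = sens, false_positive_fraction = fpf,
               objective = sens - fpf)
  }))
  best <- max(tab$objective)
  # ties broken toward the most stringent (smallest) cutoff
  chosen <- min(tab$cutoff[tab$objective >= best - 1e-12])
  list(cutoff = chosen, table = tab)
}

#' Gene-level enrichment of confident motif hits in a target gene set
#'
#' Counts, in the target and background gene sets, the genes with at
#' least one confident hit starting inside the upstream window, and tests
#' the 2x2 (hit, no hit) x (target, background) table with the two-sided
#' Fisher's exact test.
#'
#' @param classified A `hit_classification` (from [classify_hits()]), or a
#'   motif-hit data.frame already restricted to confident hits.
#' @param target_genes,background_genes Disjoint character vectors of
#'   gene ids.
#' @param window Upstream window length (default 1000).
#' @return An `enrichment_result`: counts, fractions as percentages
#'   rounded to one decimal, and the Fisher p-value.
#' @export
gene_level_enrichment <- function(classified, target_genes, background_genes,
                                  window = 1000) {
  if (length(intersect(target_genes, background_genes)))
    stop("target and background gene sets must be disjoint")
  conf <- if (inherits(classified, "hit_classification"))
    classified$confident else classified
  t_with <- sum(.genes_with_hit(conf, target_genes, window))
  b_with <- sum(.genes_with_hit(conf, background_genes, window))
  enrichment_from_counts(t_with, length(target_genes),
                         b_with, length(background_genes))
}

#' Enrichment statistics from ready-made gene counts
#'
#' @param target_with,target_total Genes with a confident hit / total, in
#'   the target set.
#' @param background_with,background_total Same for the background set.
#' @return An `enrichment_result`.
#' @export
enrichment_from_counts <- function(target_with, target_total,
                                   background_with, background_total) {
  stopifnot(target_with <= target_total, background_with <= background_total)
  structure(list(
    target_with = target_with, target_total = target_total,
    background_with = background_with, background_total = background_total,
    target_fraction = round(100 * target_with / target_total, 1),
    background_fraction = round(100 * background_with / background_total, 1),
    p = fisher_exact_two_sided(target_with, target_total - target_with,
                               background_with, background_total - background_with)
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> target %d/%d (%.1f%%) vs background %d/%d (%.1f%%), p = %.3g\n",
              x$target_with, x$target_total, x$target_fraction,
              x$background_with, x$background_total, x$background_fraction, x$p))
  invisible(x)
}

#' Association between two binary gene features
#'
#' Builds the 2x2 table of two binary per-gene features (e.g. presence of
#' a confident intron-1 motif hit vs detection of the short transcript)
#' and tests independence with the two-sided Fisher's exact test.
#'
#' @param gene_table A data.frame with one row per gene.
#' @param feature_a,feature_b Names of binary (0/1 or logical) columns;
#'   `feature_a` indexes the rows of the table, `feature_b` the columns.
#' @return A list with `table` (2x2 matrix, rows = feature_a yes/no,
#'   columns = feature_b yes/no) and `p`.
#' @export
feature_association <- function(gene_table, feature_a, feature_b) {
  a <- as.logical(gene_table[[feature_a]])
  b <- as.logical(gene_table[[feature_b]])
  if (anyNA(a) || anyNA(b)) stop("features must be binary with no missing values")
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                2, 2, byrow = TRUE,
                dimnames = list(c(feature_a, paste0("not_", feature_a)),
                                c(feature_b, paste0("not_", feature_b))))
  list(table = tab, p = fisher_exact_two_sided(tab))
}

#' Feature enrichment at the extremes of a gene ranking
#'
#' Ranks genes by a numeric column (highest first; ties broken by gene id
#' for determinism), restricted to genes where the ranked quantity is
#' present, and compares the prevalence of a binary feature between the
#' top `top_k` and bottom `bottom_k` genes with the two-sided Fisher's
#' exact test.
#'
#' @param gene_table A data.frame with columns `gene_id`, `rank_by` and
#'   `feature`.
#' @param rank_by Name of the numeric ranking column.
#' @param feature Name of the binary feature column.
#' @param top_k,bottom_k Number of genes taken from each extreme.
#' @param present Optional name of a binary column marking genes where the
#'   ranked quantity is present; by default genes with a positive,
#'   non-missing `rank_by` value are ranked.
#' @return A list with `table` (2x2 matrix, rows = feature yes/no,
#'   columns = top/bottom), `p`, and the `top`/`bottom` gene ids.
#' @export
rank_extremes_association <- function(gene_table, rank_by, feature,
                                      top_k = 10, bottom_k = 10,
                                      present = NULL) {
  val <- gene_table[[rank_by]]
  keep <- if (is.null(present)) !is.na(val) & val > 0
          else as.logical(gene_table[[present]])
  gt <- gene_table[keep, , drop = FALSE]
  if (top_k + bottom_k > nrow(gt))
    stop("top_k + bottom_k exceeds the ", nrow(gt), " ranked genes")
  ord <- order(-gt[[rank_by]], gt$gene_id)
  gt <- gt[ord, , drop = FALSE]
  top <- gt[seq_len(top_k), , drop = FALSE]
  bottom <- gt[seq.int(nrow(gt) - bottom_k + 1, nrow(gt)), , drop = FALSE]
  f_top <- sum(as.logical(top[[feature]]))
  f_bot <- sum(as.logical(bottom[[feature]]))
  tab <- matrix(c(f_top, f_bot, top_k - f_top, bottom_k - f_bot),
                2, 2, byrow = TRUE,
                dimnames = list(c(feature, paste0("not_", feature)),
                                c("top", "bottom")))
  list(table = tab, p = fisher_exact_two_sided(tab),
       top = top$gene_id, bottom = bottom$gene_id)
}
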