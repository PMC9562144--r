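# Core data model for octad dissection data.
#
# An octad is one dissected eight-spore ascus. Eight-spored fission yeasts
# (e.g. S. octosporus) undergo a post-meiotic mitosis before spore
# packaging, so the eight spores come in four genetically identical pairs.
# Genotypes are scored by replica plating of the colonies grown from
# viable spores:
#   R = carries the deletion/resistance marker (lacks the wtf+ allele)
#   S = carries the wild-type wtf+ allele (antibiotic sensitive)
#   U = unknown (always U for inviable spores, which leave no colony)

.genotypes <- c("R", "S", "U")
.spore_labels <- LETTERS[1:8]
.cross_types <- c("heterozygous", "homozygous_deletion", "homozygous_wildtype")

#' Cross metadata
#'
#' @param cross_id Unique identifier of the cross.
#' @param gene Name of the gene whose deletion segregates in the cross.
#' @param cross_type One of `"heterozygous"`, `"homozygous_deletion"`,
#'   `"homozygous_wildtype"`.
#' @param notes Free-text notes.
#' @return A `cross_info` object (named list).
#' @export
cross_info <- function(cross_id, gene = NA_character_,
                       cross_type = c("heterozygous", "homozygous_deletion",
                                      "homozygous_wildtype"),
                       notes = "") {
  cross_type <- match.arg(cross_type)
  structure(list(cross_id = as.character(cross_id),
                 gene = as.character(gene),
                 cross_type = cross_type,
                 notes = as.character(notes)),
            class = "cross_info")
}

#' Assemble a cross dataset from spore records
#'
#' Bundles the per-spore dissection records of one cross with its metadata.
#' The spore table has one row per dissected spore.
#'
#' @param info A [cross_info()] object.
#' @param spores A data.frame with columns `ascus_id`, `spore_index`
#'   (labels A–H), `viable` (logical or 0/1), `genotype` (R/S/U; `"."` and
#'   `NA` are read as U). A `cross_id` column, if present, must match
#'   `info$cross_id`.
#' @param validate Validate and normalize records (default TRUE).
#' @return A `cross_dataset` object with fields `info`, `spores` and
#'   (after [filter_octads()]) `filter_report`.
#' @export
cross_dataset <- function(info, spores, validate = TRUE) {
  stopifnot(inherits(info, "cross_info"), is.data.frame(spores))
  need <- c("ascus_id", "spore_index", "viable", "genotype")
  miss <- setdiff(need, names(spores))
  if (length(miss))
    stop("spore table is missing columns: ", paste(miss, collapse = ", "))
  if ("cross_id" %in% names(spores) &&
      any(spores$cross_id != info$cross_id))
    stop("spore table contains cross_id values other than ", info$cross_id)
  spores <- data.frame(
    cross_id = info$cross_id,
    ascus_id = as.character(spores$ascus_id),
    spore_index = as.character(spores$spore_index),
    viable = as.logical(spores$viable),
    genotype = as.character(spores$genotype),
    stringsAsFactors = FALSE
  )
  spores$genotype[is.na(spores$genotype) | spores$genotype == "."] <- "U"
  ds <- structure(list(info = info, spores = spores, filter_report = NULL),
                  class = "cross_dataset")
  if (validate) ds <- validate_octads(ds) else ds
}

#' @export
print.cross_dataset <- function(x, ...) {
  n_octads <- length(unique(x$spores$ascus_id))
  cat(sprintf("<cross_dataset> %s (%s, gene %s): %d octad(s), %d spore(s)\n",
              x$info$cross_id, x$info$cross_type, x$info$gene,
              n_octads, nrow(x$spores)))
  if (!is.null(x$filter_report)) {
    fr <- x$filter_report
    cat(sprintf("  filtered: %d input, %d incomplete, %d aberrant, %d retained\n",
                fr$n_input, fr$n_excluded_incomplete, fr$n_excluded_aberrant,
                fr$n_retained))
  }
  invisible(x)
}

#' Validate and normalize the spore records of a dataset
#'
#' Enforces the record invariants: spore labels are in A–H and unique
#' within an ascus, at most eight spores per ascus, genotypes are R/S/U,
#' and inviable spores carry genotype U (replica plating cannot genotype a
#' spore that left no colony — any other genotype on an inviable spore is
#' coerced to U with a warning).
#'
#' @param dataset A `cross_dataset`.
#' @return The dataset with normalized records.
#' @export
validate_octads <- function(dataset) {
  stopifnot(inherits(dataset, "cross_dataset"))
  sp <- dataset$spores
  bad_label <- !sp$spore_index %in% .spore_labels
  if (any(bad_label))
    stop("ascus ", sp$ascus_id[bad_label][1], ": spore_index '",
         sp$spore_index[bad_label][1], "' is not one of A-H")
  dup <- duplicated(sp[c("ascus_id", "spore_index")])
  if (any(dup))
    stop("ascus ", sp$ascus_id[dup][1], ": duplicate spore label '",
         sp$spore_index[dup][1], "'")
  bad_geno <- !sp$genotype %in% .genotypes
  if (any(bad_geno))
    stop("ascus ", sp$ascus_id[bad_geno][1], ": unknown genotype code '",
         sp$genotype[bad_geno][1], "'")
  mislabelled <- !sp$viable & sp$genotype != "U"
  if (any(mislabelled)) {
    warning(sum(mislabelled),
            " inviable spore(s) listed with a genotype; coerced to U")
    sp$genotype[mislabelled] <- "U"
  }
  n_per_ascus <- table(sp$ascus_id)
  if (any(n_per_ascus > 8))
    stop("ascus ", names(n_per_ascus)[n_per_ascus > 8][1],
         ": more than eight spores dissected")
  dataset$spores <- sp
  dataset
}

#' Filter octads by the standard spore-viability analysis rules
#'
#' Applies, in order: (1) exclusion of asci with fewer than eight dissected
#' spores (incomplete dissections); then (2), for heterozygous crosses
#' only, exclusion of octads in which more than four viable spores carry
#' one allele of the segregating locus (aberrant segregation, e.g. gene
#' conversion). Each octad is excluded under exactly one rule. Because
#' genotypes come from replica-plated colonies, "spores harboring one
#' allele" counts viable genotyped spores.
#'
#' @param dataset A validated `cross_dataset`.
#' @return The dataset with `spores` reduced to retained octads and a
#'   populated `filter_report` (counts `n_input`, `n_excluded_incomplete`,
#'   `n_excluded_aberrant`, `n_retained` and the excluded ascus ids).
#' @export
filter_octads <- function(dataset) {
  stopifnot(inherits(dataset, "cross_dataset"))
  sp <- dataset$spores
  asci <- unique(sp$ascus_id)
  n_dissected <- table(factor(sp$ascus_id, levels = asci))
  incomplete <- names(n_dissected)[n_dissected < 8]

  aberrant <- character(0)
  if (dataset$info$cross_type == "heterozygous") {
    rest <- sp[!sp$ascus_id %in% incomplete & sp$viable, , drop = FALSE]
    for (allele in c("R", "S")) {
      cnt <- table(factor(rest$ascus_id[rest$genotype == allele],
                          levels = setdiff(asci, incomplete)))
      aberrant <- union(aberrant, names(cnt)[cnt > 4])
    }
  }
  retained <- setdiff(asci, c(incomplete, aberrant))
  dataset$spores <- sp[sp$ascus_id %in% retained, , drop = FALSE]
  dataset$filter_report <- list(
    cross_id = dataset$info$cross_id,
    n_input = length(asci),
    n_excluded_incomplete = length(incomplete),
    n_excluded_aberrant = length(aberrant),
    n_retained = length(retained),
    excluded_incomplete = incomplete,
    excluded_aberrant = aberrant
  )
  dataset
}

#' Classify the octads of a heterozygous cross by viable-spore genotype
#'
#' Assigns each retained octad its nRmS type: `r` viable spores carrying
#' the deletion marker (R) and `s` viable spores carrying the wild-type
#' allele (S), labelled e.g. `"4R3S"`.
#'
#' @param dataset A filtered heterozygous `cross_dataset`.
#' @param allow_ungenotyped If FALSE (default), a viable spore with
#'   genotype U is an error; if TRUE, octads containing such spores are
#'   skipped with a warning.
#' @return A data.frame with columns `ascus_id`, `r`, `s`, `label`.
#' @export
classify_octads <- function(dataset, allow_ungenotyped = FALSE) {
  stopifnot(inherits(dataset, "cross_dataset"))
  if (dataset$info$cross_type != "heterozygous")
    stop("octad-type classification applies to heterozygous crosses only")
  if (is.null(dataset$filter_report))
    stop("dataset must be filtered with filter_octads() before classification")
  sp <- dataset$spores
  asci <- unique(sp$ascus_id)
  ungeno <- unique(sp$ascus_id[sp$viable & sp$genotype == "U"])
  if (length(ungeno)) {
    if (!allow_ungenotyped)
      stop("ascus ", ungeno[1], ": viable spore without genotype; ",
           "set allow_ungenotyped = TRUE to skip such octads")
    warning("skipping ", length(ungeno), " octad(s) with viable ungenotyped spores")
    asci <- setdiff(asci, ungeno)
  }
  viable <- sp[sp$viable & sp$ascus_id %in% asci, , drop = FALSE]
  r <- as.integer(table(factor(viable$ascus_id[viable$genotype == "R"], levels = asci)))
  s <- as.integer(table(factor(viable$ascus_id[viable$genotype == "S"], levels = asci)))
  data.frame(ascus_id = asci, r = r, s = s,
             label = sprintf("%dR%dS", r, s),
             stringsAsFactors = FALSE)
}

#' Tabulate octad-type counts for a heterozygous cross
#'
#' @param dataset A filtered heterozygous `cross_dataset`.
#' @param allow_ungenotyped Passed to [classify_octads()].
#' @return An `octad_type_counts` object: the cross id and a 5x5 integer
#'   matrix of counts, rows = viable R spores (0–4), columns = viable S
#'   spores (0–4). Counts sum to the number of retained (classifiable)
#'   octads.
#' @export
tabulate_types <- function(dataset, allow_ungenotyped = FALSE) {
  cls <- classify_octads(dataset, allow_ungenotyped = allow_ungenotyped)
  octad_type_counts(cls$r, cls$s, cross_id = dataset$info$cross_id)
}

#' Build an octad-type count table from (r, s) pairs or a counts matrix
#'
#' @param r,s Integer vectors of viable R and S counts per octad (both in
#'   0–4), or `r` may be a ready-made 5x5 counts matrix with `s` missing.
#' @param cross_id Cross identifier carried along.
#' @return An `octad_type_counts` object.
#' @export
octad_type_counts <- function(r, s = NULL, cross_id = NA_character_) {
  if (is.matrix(r) && is.null(s)) {
    stopifnot(identical(dim(r), c(5L, 5L)), all(r >= 0))
    counts <- r
  } else {
    stopifnot(length(r) == length(s), all(r %in% 0:4), all(s %in% 0:4))
    counts <- unclass(table(factor(r, levels = 0:4), factor(s, levels = 0:4)))
  }
  dimnames(counts) <- list(r = 0:4, s = 0:4)
  structure(list(cross_id = as.character(cross_id),
                 counts = counts,
                 n_octads = sum(counts)),
            class = "octad_type_counts")
}

#' @export
print.octad_type_counts <- function(x, ...) {
  cat(sprintf("<octad_type_counts> cross %s, %d octad(s)\n",
              x$cross_id, x$n_octads))
  print(x$counts)
  invisible(x)
}
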