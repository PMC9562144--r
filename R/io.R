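# File formats: tab-separated octad and cross tables (the dialect of
# dissection source-data tables), report serialization to TSV and JSON.
# "." is the missing-value token throughout.

#' Read an octad dissection table
#'
#' Reads a TSV with one row per dissected spore and columns `cross_id`,
#' `ascus_id`, `spore_index` (A–H), `viable` (0/1) and `genotype`
#' (R/S/U, `.` = missing, read as U), and groups the rows into one
#' `cross_dataset` per cross. Cross metadata is taken from `crosses`
#' when given, otherwise every cross is assumed heterozygous.
#'
#' @param path Path to the octad TSV.
#' @param crosses Optional cross-metadata data.frame (see
#'   [read_cross_table()]) with columns `cross_id`, `gene`, `cross_type`,
#'   `notes`.
#' @return A named list of validated `cross_dataset` objects.
#' @export
read_octad_table <- function(path, crosses = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  need <- c("cross_id", "ascus_id", "spore_index", "viable", "genotype")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("octad table ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  bad <- which(!tab$viable %in% c("0", "1"))
  if (length(bad))
    stop("octad table ", path, " line ", bad[1] + 1,
         ": viable must be 0 or 1, got '", tab$viable[bad[1]], "'")
  bad <- which(!tab$genotype %in% c("R", "S", "U", "."))
  if (length(bad))
    stop("octad table ", path, " line ", bad[1] + 1,
         ": unknown genotype code '", tab$genotype[bad[1]], "'")
  key <- paste(tab$cross_id, tab$ascus_id, tab$spore_index)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("octad table ", path, " line ", dup[1] + 1,
         ": duplicate (cross, ascus, spore) record")
  tab$viable <- tab$viable == "1"
  tab$genotype[tab$genotype == "."] <- "U"
  lapply(split(tab, tab$cross_id), function(sub) {
    id <- sub$cross_id[1]
    info <- if (!is.null(crosses) && id %in% crosses$cross_id) {
      row <- crosses[crosses$cross_id == id, ]
      cross_info(id, row$gene[1], row$cross_type[1], row$notes[1])
    } else cross_info(id)
    cross_dataset(info, sub)
  })
}

#' Read a cross-metadata table
#'
#' TSV with columns `cross_id`, `gene`, `cross_type` (one of
#' `heterozygous`, `homozygous_deletion`, `homozygous_wildtype`) and
#' optional `notes`.
#'
#' @param path Path to the cross TSV.
#' @return A data.frame.
#' @export
read_cross_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = ".")
  need <- c("cross_id", "gene", "cross_type")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("cross table ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  bad <- which(!tab$cross_type %in% .cross_types)
  if (length(bad))
    stop("cross table ", path, " line ", bad[1] + 1,
         ": unknown cross_type '", tab$cross_type[bad[1]], "'")
  if (anyDuplicated(tab$cross_id))
    stop("cross table ", path, ": duplicate cross_id")
  if (!"notes" %in% names(tab)) tab$notes <- ""
  tab
}

#' Write one or more cross datasets as an octad table
#'
#' Inverse of [read_octad_table()]: one row per spore, deterministic row
#' and column order, `.` for unknown genotypes.
#'
#' @param datasets A `cross_dataset` or list of them.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_octad_table <- function(datasets, path) {
  if (inherits(datasets, "cross_dataset")) datasets <- list(datasets)
  sp <- do.call(rbind, lapply(datasets, function(d) d$spores))
  sp <- sp[order(sp$cross_id, sp$ascus_id, sp$spore_index), ]
  sp$viable <- as.integer(sp$viable)
  sp$genotype[sp$genotype == "U"] <- "."
  utils::write.table(sp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.report_row <- function(r) {
  data.frame(
    cross_id = r$cross_id, gene = r$gene,
    viable = r$viability$viable, dissected = r$viability$dissected,
    viability = r$viability$fraction,
    control_viable = r$control_viability$viable,
    control_dissected = r$control_viability$dissected,
    control_viability = r$control_viability$fraction,
    reduction_pp = r$reduction_pp, p_viability = r$p_viability,
    n_viable_R = r$n_viable_R, n_viable_S = r$n_viable_S,
    tdr = r$tdr, p_transmission = r$p_transmission,
    status = r$status, stringsAsFactors = FALSE
  )
}

#' Write drive reports to TSV and JSON
#'
#' Writes `reports.tsv` (one row per cross, deterministic column order)
#' and `reports.json` (full reports including the mirror-pair ratio
#' tests, with gated pairs carrying a null p and reason
#' `"gated_total_le_5"`, plus run metadata).
#'
#' @param reports A `drive_report` or list of them.
#' @param dir Output directory (created if needed).
#' @param run_config Optional named list of run settings embedded in the
#'   JSON metadata (e.g. seed, alpha).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_reports <- function(reports, dir, run_config = list()) {
  if (inherits(reports, "drive_report")) reports <- list(reports)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "reports.tsv")
  json <- file.path(dir, "reports.json")
  rows <- if (length(reports)) do.call(rbind, lapply(reports, .report_row))
          else .report_row(.empty_report())[0, ]
  utils::write.table(rows, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  payload <- list(
    metadata = c(list(package = "octadrive",
                      version = as.character(utils::packageVersion("octadrive"))),
                 run_config),
    reports = lapply(reports, function(r) {
      rt <- r$ratio_tests
      list(cross_id = r$cross_id, gene = r$gene,
           viability = r$viability, control_viability = r$control_viability,
           reduction_pp = r$reduction_pp, p_viability = r$p_viability,
           n_viable_R = r$n_viable_R, n_viable_S = r$n_viable_S,
           tdr = r$tdr, p_transmission = r$p_transmission,
           status = r$status,
           ratio_tests = lapply(seq_len(nrow(rt)), function(i) {
             x <- list(pair = rt$pair[i], n_first = rt$n_first[i],
                       n_second = rt$n_second[i], total = rt$total[i])
             if (rt$gated[i]) x$reason <- "gated_total_le_5" else x$p <- rt$p[i]
             x
           }))
    })
  )
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}

.empty_report <- function() {
  structure(list(cross_id = "", gene = "",
                 viability = list(viable = 0L, dissected = 0L, fraction = NA_real_),
                 control_viability = list(viable = 0L, dissected = 0L, fraction = NA_real_),
                 reduction_pp = NA_real_, p_viability = NA_real_,
                 n_viable_R = 0L, n_viable_S = 0L, tdr = NA_real_,
                 p_transmission = NA_real_,
                 ratio_tests = NULL, status = ""), class = "drive_report")
}

#' Serialize a filter report
#'
#' @param report The `filter_report` field of a filtered `cross_dataset`,
#'   or a list of such reports.
#' @return A data.frame with one row per cross (counts only; excluded ids
#'   are collapsed comma-separated).
#' @export
filter_report_table <- function(report) {
  if (!is.null(report$cross_id)) report <- list(report)
  do.call(rbind, lapply(report, function(fr) {
    data.frame(cross_id = fr$cross_id, n_input = fr$n_input,
               n_excluded_incomplete = fr$n_excluded_incomplete,
               n_excluded_aberrant = fr$n_excluded_aberrant,
               n_retained = fr$n_retained,
               excluded_ids = paste(c(fr$excluded_incomplete,
                                      fr$excluded_aberrant), collapse = ","),
               stringsAsFactors = FALSE)
  }))
}
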