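# TSV/JSON readers and writers for cohort tables.

#' Write a cohort to a directory
#'
#' Writes `proteins.tsv` (subjects x analytes, first column the subject
#' identifier, empty cell = missing), `phenotypes.tsv`, `lod.tsv`
#' (analyte, lower, upper; written when limits exist) and, when ground
#' truth is present, `truth.json`.
#'
#' @param cohort List with `proteins`, `phenotypes` and optionally
#'   `truth` as returned by [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pm <- cohort$proteins
  df <- data.frame(subject_id = rownames(pm$values), pm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file.path(dir, "proteins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(cohort$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(pm$lod)) {
    utils::write.table(pm$lod, file.path(dir, "lod.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    jsonlite::write_json(
      list(partition = as.list(tr$partition),
           planted_effects = tr$planted_effects,
           status_effects = tr$status_effects,
           loadings = as.list(tr$loadings)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a protein matrix from TSV
#'
#' Expects the layout written by [write_cohort()]: first column subject
#' identifiers, remaining columns analytes, empty cells missing. When a
#' detection-limit table is supplied, observed values at or below the
#' lower limit (or at or above the upper limit) are flagged censored.
#'
#' @param proteins_path Path to `proteins.tsv`.
#' @param lod_path Optional path to `lod.tsv`.
#' @return A `protein_matrix` at stage `raw`.
#' @export
read_protein_matrix <- function(proteins_path, lod_path = NULL) {
  if (!file.exists(proteins_path)) {
    stop(sprintf("file not found: %s", proteins_path), call. = FALSE)
  }
  df <- utils::read.delim(proteins_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- as.character(df[[1]])
  lod <- NULL
  censor <- NULL
  if (!is.null(lod_path)) {
    if (!file.exists(lod_path)) {
      stop(sprintf("file not found: %s", lod_path), call. = FALSE)
    }
    lod <- utils::read.delim(lod_path, stringsAsFactors = FALSE)
    censor <- matrix("none", nrow(X), ncol(X), dimnames = dimnames(X))
    for (j in seq_len(ncol(X))) {
      lims <- lod[lod$analyte == colnames(X)[j], ]
      if (nrow(lims) != 1) next
      if (!is.na(lims$lower)) {
        censor[!is.na(X[, j]) & X[, j] <= lims$lower, j] <- "low"
      }
      if (!is.na(lims$upper)) {
        censor[!is.na(X[, j]) & X[, j] >= lims$upper, j] <- "high"
      }
    }
  }
  protein_matrix(X, is.na(X), censor, lod, stage = "raw")
}

#' Read a phenotype table from TSV
#'
#' @param path Path to `phenotypes.tsv`.
#' @return Data frame with `status` as a factor (control, remitted,
#'   current) and `batch`/`site`/`sex` as factors.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$status <- factor(df$status, levels = c("control", "remitted", "current"))
  for (v in c("batch", "site", "sex")) {
    if (v %in% names(df)) df[[v]] <- factor(df[[v]])
  }
  df
}
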