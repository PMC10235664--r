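#' Construct a protein matrix container
#'
#' Holds a subjects x analytes numeric matrix together with a per-cell
#' missingness mask, per-cell detection-limit censoring flags, optional
#' detection-limit metadata, and a processing stage marker (`raw`,
#' `imputed` or `transformed`).
#'
#' @param values Numeric matrix, subjects in rows, analytes in columns;
#'   must have row and column names.
#' @param missing Logical matrix of the same shape marking missing
#'   cells; missing cells carry `NA` in `values` at stage `raw`.
#' @param censor Character matrix of the same shape with entries
#'   `"none"`, `"low"` or `"high"` marking detection-limit censoring.
#' @param lod Optional data frame with columns `analyte`, `lower`,
#'   `upper` (either limit may be `NA`).
#' @param stage One of `"raw"`, `"imputed"`, `"transformed"`.
#' @return A `protein_matrix` object.
#' @export
protein_matrix <- function(values, missing = NULL, censor = NULL,
                           lod = NULL, stage = "raw") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry subject row names and analyte column names",
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("analyte identifiers must be unique", call. = FALSE)
  }
  stage <- match.arg(stage, c("raw", "imputed", "transformed"))
  if (is.null(missing)) {
    missing <- is.na(values)
  }
  if (!identical(dim(missing), dim(values))) {
    stop("`missing` mask shape must match `values`", call. = FALSE)
  }
  if (is.null(censor)) {
    censor <- matrix("none", nrow(values), ncol(values),
                     dimnames = dimnames(values))
  }
  if (!identical(dim(censor), dim(values)) ||
      !all(censor %in% c("none", "low", "high"))) {
    stop("`censor` must match `values` with entries none/low/high",
         call. = FALSE)
  }
  if (!is.null(lod)) {
    if (!is.data.frame(lod) ||
        !all(c("analyte", "lower", "upper") %in% names(lod))) {
      stop("`lod` needs columns analyte, lower, upper", call. = FALSE)
    }
  }
  if (stage != "raw" && any(missing & is.na(values))) {
    stop("no missing cells allowed at stage >= imputed", call. = FALSE)
  }
  dimnames(missing) <- dimnames(values)
  structure(list(values = values, missing = missing, censor = censor,
                 lod = lod, stage = stage),
            class = "protein_matrix")
}

#' @export
dim.protein_matrix <- function(x) dim(x$values)

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf(
    "<protein_matrix> %d subjects x %d analytes, stage=%s\n",
    nrow(x$values), ncol(x$values), x$stage))
  cat(sprintf("  missing cells: %d (%.1f%%), censored cells: %d\n",
              sum(x$missing), 100 * mean(x$missing),
              sum(x$censor != "none")))
  invisible(x)
}

analyte_ids <- function(x) colnames(x$values)
subject_ids <- function(x) rownames(x$values)

# subset analytes (columns), keeping masks and lod in step
subset_analytes <- function(x, keep) {
  lod <- x$lod
  if (!is.null(lod)) {
    kept <- colnames(x$values)[keep]
    lod <- lod[lod$analyte %in% kept, , drop = FALSE]
  }
  protein_matrix(x$values[, keep, drop = FALSE],
                 x$missing[, keep, drop = FALSE],
                 x$censor[, keep, drop = FALSE],
                 lod, x$stage)
}

# subset subjects (rows)
subset_subjects <- function(x, keep) {
  protein_matrix(x$values[keep, , drop = FALSE],
                 x$missing[keep, , drop = FALSE],
                 x$censor[keep, , drop = FALSE],
                 x$lod, x$stage)
}
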