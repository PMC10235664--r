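# Analyte filtering, detection-limit and median imputation, and the
# rank-based inverse-normal transform applied before network construction.

#' Exclude analytes with excessive missingness
#'
#' Analytes whose missing fraction is strictly greater than the
#' threshold (default 30%) are removed; an analyte with exactly the
#' threshold fraction is retained. Cells flagged censored with a known
#' detection limit count as observed (they are imputable data); a
#' censored cell with no limit on record counts as missing.
#'
#' @param proteins A `protein_matrix` at stage `raw`.
#' @param config A [preprocess_config()].
#' @return A list with `proteins` (surviving analytes, original order)
#'   and `excluded` (data frame: analyte, missing fraction).
#' @export
filter_by_missingness <- function(proteins, config = preprocess_config()) {
  if (proteins$stage != "raw") stop("expected stage `raw`", call. = FALSE)
  miss <- proteins$missing
  if (!is.null(proteins$lod)) {
    lower <- proteins$lod$lower[match(colnames(proteins$values),
                                      proteins$lod$analyte)]
    upper <- proteins$lod$upper[match(colnames(proteins$values),
                                      proteins$lod$analyte)]
  } else {
    lower <- upper <- rep(NA_real_, ncol(proteins$values))
  }
  unresolved <- sweep(proteins$censor == "low", 2, is.na(lower), `&`) |
    sweep(proteins$censor == "high", 2, is.na(upper), `&`)
  frac <- colMeans(miss | unresolved)
  drop <- frac > config$missing_threshold
  if (all(drop)) stop("no analytes survive filter", call. = FALSE)
  excluded <- data.frame(analyte = colnames(proteins$values)[drop],
                         missing_fraction = frac[drop],
                         row.names = NULL, stringsAsFactors = FALSE)
  list(proteins = subset_analytes(proteins, !drop), excluded = excluded)
}

#' Impute censored and missing cells
#'
#' Censored-low cells receive the analyte's lower detection limit and
#' censored-high cells the upper limit; the remaining missing cells
#' receive the median of that analyte's observed, non-censored values.
#' Censored values are resolved first and excluded from the median,
#' since a value at the detection boundary is not a valid
#' central-tendency observation.
#'
#' @param proteins A `protein_matrix` at stage `raw` (post-filter).
#' @return A `protein_matrix` at stage `imputed` with no missing cells.
#' @export
impute_matrix <- function(proteins) {
  if (proteins$stage != "raw") stop("expected stage `raw`", call. = FALSE)
  X <- proteins$values
  ids <- colnames(X)
  lod <- proteins$lod
  for (j in seq_along(ids)) {
    cl <- proteins$censor[, j] == "low"
    ch <- proteins$censor[, j] == "high"
    if (any(cl) || any(ch)) {
      if (is.null(lod) || !ids[j] %in% lod$analyte) {
        stop(sprintf("censored cells in `%s` but no detection limits on record",
                     ids[j]), call. = FALSE)
      }
      lims <- lod[lod$analyte == ids[j], ]
      if (any(cl)) {
        if (is.na(lims$lower)) {
          stop(sprintf("censored-low cells in `%s` but no lower limit", ids[j]),
               call. = FALSE)
        }
        X[cl, j] <- lims$lower
      }
      if (any(ch)) {
        if (is.na(lims$upper)) {
          stop(sprintf("censored-high cells in `%s` but no upper limit", ids[j]),
               call. = FALSE)
        }
        X[ch, j] <- lims$upper
      }
    }
    mi <- proteins$missing[, j]
    if (any(mi)) {
      obs <- X[!mi & !cl & !ch, j]
      if (length(obs) == 0L) {
        stop(sprintf("analyte `%s` has no observed values to impute from",
                     ids[j]), call. = FALSE)
      }
      X[mi, j] <- stats::median(obs)
    }
  }
  protein_matrix(X, matrix(FALSE, nrow(X), ncol(X)), proteins$censor,
                 lod, stage = "imputed")
}

#' Rank-based inverse-normal (Blom) transform
#'
#' Per analyte, values are replaced by
#' \eqn{\Phi^{-1}((r - c)/(n - 2c + 1))} where r is the average rank
#' (ties share their mean rank) and c is the Blom offset 3/8. The
#' transform is variance-stabilizing and preserves the rank order of
#' untied values.
#'
#' @param proteins A `protein_matrix` at stage `imputed` (no missing
#'   cells). A stage-`transformed` input is accepted so the transform
#'   is idempotent on tie-free data.
#' @param config A [preprocess_config()].
#' @return A `protein_matrix` at stage `transformed`.
#' @export
inverse_normal_transform <- function(proteins, config = preprocess_config()) {
  if (proteins$stage == "raw") {
    stop("expected stage `imputed` (run impute_matrix first)", call. = FALSE)
  }
  X <- proteins$values
  if (anyNA(X)) stop("matrix contains missing cells", call. = FALSE)
  n <- nrow(X)
  c0 <- config$blom_offset
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    if (max(x) == min(x)) {
      stop(sprintf("analyte `%s` has zero variance", colnames(X)[j]),
           call. = FALSE)
    }
    r <- rank(x, ties.method = "average")
    X[, j] <- stats::qnorm((r - c0) / (n - 2 * c0 + 1))
  }
  protein_matrix(X, matrix(FALSE, n, ncol(X)), proteins$censor,
                 proteins$lod, stage = "transformed")
}

#' Run the full preprocessing pipeline
#'
#' Missingness filter, then imputation, then the inverse-normal
#' transform.
#'
#' @inheritParams filter_by_missingness
#' @return A list with `proteins` (stage `transformed`) and `excluded`.
#' @export
preprocess <- function(proteins, config = preprocess_config()) {
  flt <- filter_by_missingness(proteins, config)
  imp <- impute_matrix(flt$proteins)
  list(proteins = inverse_normal_transform(imp, config),
       excluded = flt$excluded)
}
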