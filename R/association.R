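# Tiered covariate-adjusted linear contrasts of eigenproteins against
# diagnosis status and dichotomized symptom items, with Bonferroni control.

#' Covariates per adjustment tier
#'
#' `base` adjusts for batch, site, sex, age and education; `lifestyle`
#' adds chronic diseases, smoking, alcohol and physical activity; `bmi`
#' further adds BMI.
#'
#' @param tier One of `"base"`, `"lifestyle"`, `"bmi"`.
#' @return Character vector of covariate column names.
#' @export
tier_covariates <- function(tier = c("base", "lifestyle", "bmi")) {
  tier <- match.arg(tier)
  base <- c("batch", "site", "sex", "age", "education")
  lifestyle <- c(base, "chronic_diseases", "smoking", "alcohol",
                 "physical_activity")
  switch(tier, base = base, lifestyle = lifestyle, bmi = c(lifestyle, "bmi"))
}

#' Build the 4-level symptom factor for one item
#'
#' Controls and remitted subjects keep their status; current-status
#' subjects are split by the item score into `current_high` (score 2 or
#' 3) and `current_low` (score 0 or 1). Current subjects with a missing
#' item score are dropped (set `NA`) with a warning.
#'
#' @param phenotypes Phenotype data frame with `status` and item
#'   columns `ids_01..ids_30`.
#' @param item_index Integer in 1..30.
#' @return Factor with levels control, remitted, current_low,
#'   current_high, aligned with `phenotypes` rows; attribute `counts`
#'   holds the per-level counts.
#' @export
build_symptom_factor <- function(phenotypes, item_index) {
  check_count(item_index, "item_index", min = 1L)
  col <- sprintf("ids_%02d", item_index)
  if (!col %in% names(phenotypes)) {
    stop(sprintf("item column `%s` not found", col), call. = FALSE)
  }
  item <- phenotypes[[col]]
  if (any(!is.na(item) & !item %in% 0:3)) {
    stop(sprintf("item `%s` has scores outside 0..3", col), call. = FALSE)
  }
  status <- phenotypes$status
  out <- rep(NA_character_, nrow(phenotypes))
  out[status == "control"] <- "control"
  out[status == "remitted"] <- "remitted"
  cur <- which(status == "current")
  miss <- cur[is.na(item[cur])]
  if (length(miss)) {
    warning(sprintf("%d current-status subject(s) dropped: missing item %s",
                    length(miss), col))
  }
  keep <- setdiff(cur, miss)
  out[keep] <- ifelse(item[keep] >= 2, "current_high", "current_low")
  f <- factor(out, levels = c("control", "remitted", "current_low",
                              "current_high"))
  attr(f, "counts") <- table(f)
  f
}

.contrast_term <- c(current_vs_control = "current",
                    current_high_vs_control = "current_high",
                    current_low_vs_control = "current_low")

#' Fit one covariate-adjusted contrast
#'
#' Ordinary least squares of an eigenprotein on a grouping factor
#' (treatment-coded, control as reference) plus the tier's covariates.
#' The reported result is the contrasted group's coefficient: its
#' estimate, standard error, t statistic and two-sided p-value.
#' Subjects with a missing outcome, factor level or covariate are
#' dropped (complete-case per model); the n used is recorded.
#'
#' @param y Numeric eigenprotein scores aligned with `phenotypes` rows.
#' @param fac Grouping factor with reference level `control` (e.g.
#'   status, or the output of [build_symptom_factor()]).
#' @param phenotypes Phenotype data frame supplying covariates.
#' @param tier Adjustment tier, see [tier_covariates()].
#' @param contrast One of `"current_vs_control"`,
#'   `"current_high_vs_control"`, `"current_low_vs_control"`.
#' @return One-row data frame: contrast, tier, estimate, se, t, p,
#'   n_used.
#' @export
fit_contrast <- function(y, fac, phenotypes,
                         tier = c("base", "lifestyle", "bmi"),
                         contrast = names(.contrast_term)) {
  tier <- match.arg(tier)
  contrast <- match.arg(contrast)
  level <- .contrast_term[[contrast]]
  covs <- tier_covariates(tier)
  covs <- covs[covs %in% names(phenotypes)]
  dat <- data.frame(.y = y, .g = fac, phenotypes[, covs, drop = FALSE])
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  dat$.g <- droplevels(dat$.g)
  if (!level %in% levels(dat$.g) || !"control" %in% levels(dat$.g)) {
    stop(sprintf("contrast `%s` needs groups `control` and `%s` present",
                 contrast, level), call. = FALSE)
  }
  if (min(table(dat$.g)[c("control", level)]) < 2L) {
    stop("each contrasted group needs >= 2 subjects", call. = FALSE)
  }
  dat$.g <- stats::relevel(dat$.g, ref = "control")
  form <- if (length(covs)) {
    stats::as.formula(paste(".y ~ .g +", paste(covs, collapse = " + ")))
  } else .y ~ .g
  fit <- stats::lm(form, data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop(sprintf("rank-deficient design; aliased: %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")),
         call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  term <- paste0(".g", level)
  data.frame(contrast = contrast, tier = tier,
             estimate = sm[term, "Estimate"],
             se = sm[term, "Std. Error"],
             t = sm[term, "t value"],
             p = sm[term, "Pr(>|t|)"],
             n_used = nrow(dat),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bonferroni adjustment
#'
#' Multiplies the p-value by the number of tests, clipped at 1.
#'
#' @param p P-value(s) in [0, 1].
#' @param multiplier Number of tests (integer >= 1).
#' @return Adjusted p-value(s).
#' @export
bonferroni_adjust <- function(p, multiplier) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop_bad("p", "must be in [0, 1]")
  }
  check_count(multiplier, "multiplier", min = 1L)
  pmin(1, p * multiplier)
}

#' Scan all modules against current diagnosis
#'
#' One current-vs-control contrast per module eigenprotein, Bonferroni
#' multiplier equal to the module count. The minimum-p module is
#' flagged (`selected`).
#'
#' @param eigenproteins An `eigenprotein_set` or a scores matrix.
#' @param phenotypes Phenotype data frame with `status` and covariates.
#' @param tier Adjustment tier.
#' @return Data frame, one row per module, with Bonferroni-adjusted
#'   p-values, the multiplier, and a `selected` flag.
#' @export
scan_clusters_vs_status <- function(eigenproteins, phenotypes,
                                    tier = c("base", "lifestyle", "bmi")) {
  tier <- match.arg(tier)
  S <- if (inherits(eigenproteins, "eigenprotein_set")) {
    eigenproteins$scores
  } else eigenproteins
  K <- ncol(S)
  if (K < 1) stop("need at least one module", call. = FALSE)
  fac <- factor(phenotypes$status, levels = c("control", "remitted", "current"))
  rows <- lapply(seq_len(K), function(m) {
    r <- fit_contrast(S[, m], fac, phenotypes, tier, "current_vs_control")
    cbind(module = colnames(S)[m], r)
  })
  out <- do.call(rbind, rows)
  out$multiplier <- K
  out$p_bonferroni <- bonferroni_adjust(out$p, K)
  out$selected <- out$p == min(out$p)
  out
}

#' Scan symptom items for selected module(s)
#'
#' For each (module, item) pair, contrasts either the current-high or
#' the current-low endorsement group against controls on the 4-level
#' symptom factor. The Bonferroni multiplier is the number of items
#' scanned times the number of modules scanned.
#'
#' @param eigenproteins Scores matrix (or `eigenprotein_set`) restricted
#'   to the module(s) selected by the status scan.
#' @param phenotypes Phenotype data frame.
#' @param tier Adjustment tier.
#' @param contrast `"current_high_vs_control"` or
#'   `"current_low_vs_control"`.
#' @param symptom_items Integer vector of item indices to scan. The
#'   default scans items 1..28 (28 of the 30 items); which items enter
#'   is study configuration, and the count used is recorded.
#' @return Data frame sorted by p, one row per (module, item), with the
#'   multiplier and Bonferroni-adjusted p-values.
#' @export
scan_symptoms <- function(eigenproteins, phenotypes,
                          tier = c("base", "lifestyle", "bmi"),
                          contrast = c("current_high_vs_control",
                                       "current_low_vs_control"),
                          symptom_items = 1:28) {
  tier <- match.arg(tier)
  contrast <- match.arg(contrast)
  S <- if (inherits(eigenproteins, "eigenprotein_set")) {
    eigenproteins$scores
  } else eigenproteins
  if (is.null(dim(S))) S <- matrix(S, ncol = 1, dimnames = list(NULL, "EP"))
  mult <- length(symptom_items) * ncol(S)
  rows <- list()
  for (m in seq_len(ncol(S))) {
    for (it in symptom_items) {
      fac <- build_symptom_factor(phenotypes, it)
      r <- fit_contrast(S[, m], fac, phenotypes, tier, contrast)
      rows[[length(rows) + 1L]] <-
        cbind(module = colnames(S)[m], item = sprintf("ids_%02d", it), r)
    }
  }
  out <- do.call(rbind, rows)
  out$multiplier <- mult
  out$p_bonferroni <- bonferroni_adjust(out$p, mult)
  out[order(out$p), ]
}
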