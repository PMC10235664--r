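# Synthetic cohort generator: latent-factor protein blocks, a three-level
# diagnostic status, ordinal symptom items driven by an ordered logit, and
# covariates with plausible marginals. The generator defines the study
# conditions every downstream stage is validated against.

# ordered-logit cut points on the logistic liability scale (item scores 0-3)
.item_thresholds <- c(-1, 2, 4)
# status intercepts on the liability scale
.status_theta <- c(control = -2, remitted = -0.7, current = 0.8)

#' Generate a synthetic cohort
#'
#' Each correlated block m has a latent standard-normal factor f_m per
#' subject; analyte j of block m equals lambda_j * f_m + noise, with a
#' configured fraction of sign-flipped loadings. Background analytes are
#' independent standard normal. Symptom items (30, scored 0-3) arise
#' from an ordered logit on a liability combining a status intercept
#' and, for planted (module, symptom) pairs, the module factor among
#' current-status subjects. Status may also shift module factors
#' directly (`status_effects`), giving the module a diagnosis
#' association. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `proteins` (a complete, uncensored
#'   [protein_matrix()] at stage `raw`), `phenotypes` (data frame) and
#'   `truth` (true partition, factor scores, loadings and the planted
#'   effect table).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be a sim_config object", call. = FALSE)
  }
  seeds <- seed_streams(config$seed,
                        c("status", "factors", "loadings", "noise",
                          "symptoms", "covariates", "missing", "censor"))
  n <- config$n_subjects
  p <- config$n_analytes
  spec <- config$module_spec
  K <- nrow(spec)
  subj <- sprintf("S%04d", seq_len(n))
  anly <- sprintf("prot_%03d", seq_len(p))

  # diagnostic status with largest-remainder apportionment of prevalence
  counts <- floor(config$prevalence * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- config$prevalence * n - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  status <- with_seed(seeds["status"], sample(rep(names(counts), counts)))
  status <- factor(status, levels = c("control", "remitted", "current"))

  # latent factors, optionally shifted by status
  FS <- with_seed(seeds["factors"], matrix(stats::rnorm(n * max(K, 1)), n, max(K, 1)))
  se <- config$status_effects
  if (K > 0 && is.data.frame(se) && nrow(se) > 0) {
    for (i in seq_len(nrow(se))) {
      m <- se$module[i]
      if (m >= 1 && m <= K) {
        FS[, m] <- FS[, m] + se$remitted[i] * (status == "remitted") +
          se$current[i] * (status == "current")
      }
    }
  }

  # loadings: constant magnitude per block, exact count of sign flips
  partition <- stats::setNames(integer(p), anly)
  lambda <- stats::setNames(numeric(p), anly)
  j <- 0L
  load_signs <- with_seed(seeds["loadings"], lapply(seq_len(K), function(m) {
    sz <- spec$size[m]
    nneg <- round(spec$frac_negative[m] * sz)
    sgn <- rep(1, sz)
    if (nneg > 0) sgn[sample.int(sz, nneg)] <- -1
    sgn
  }))
  X <- with_seed(seeds["noise"],
                 matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p))
  for (m in seq_len(K)) {
    for (s in seq_len(spec$size[m])) {
      j <- j + 1L
      lam <- spec$loading_mean[m] * load_signs[[m]][s]
      partition[j] <- m
      lambda[j] <- lam
      X[, j] <- lam * FS[, m] + X[, j]
    }
  }
  if (j < p) {
    # background analytes: independent unit-variance noise
    X[, (j + 1L):p] <- with_seed(
      seeds["noise"] + 1L, matrix(stats::rnorm(n * (p - j)), n, p - j))
  }
  dimnames(X) <- list(subj, anly)

  # symptom items via ordered logit on status + planted factor effects
  pe <- config$planted_effects
  items <- with_seed(seeds["symptoms"], {
    it <- matrix(0L, n, 30L, dimnames = list(subj, sprintf("ids_%02d", 1:30)))
    for (s in 1:30) {
      liab <- .status_theta[as.character(status)] + stats::rlogis(n)
      if (K > 0 && nrow(pe) > 0) {
        rows <- which(pe$symptom == s)
        for (r in rows) {
          # planted effect acts among current-status subjects
          liab <- liab + pe$effect[r] * FS[, pe$module[r]] * (status == "current")
        }
      }
      it[, s] <- findInterval(liab, .item_thresholds)
    }
    it
  })

  covs <- with_seed(seeds["covariates"], {
    cur <- status == "current"
    bmi <- stats::rnorm(n, 25 + 1.0 * cur, 4)
    if (K >= 2 && config$bmi_coupling != 0) {
      bmi <- bmi + config$bmi_coupling * FS[, 2]
    }
    data.frame(
      batch = factor(sample.int(26L, n, replace = TRUE)),
      site = factor(sample.int(5L, n, replace = TRUE)),
      sex = factor(sample(c("female", "male"), n, TRUE, prob = c(0.66, 0.34))),
      age = round(stats::runif(n, 18, 65)),
      education = pmin(pmax(round(stats::rnorm(n, 12, 3)), 5), 22),
      chronic_diseases = stats::rpois(n, 0.5 + 0.3 * cur),
      smoking = stats::rbinom(n, 1, 0.30 + 0.12 * cur),
      alcohol = stats::rpois(n, 5),
      physical_activity = round(stats::rlnorm(n, 7.8 - 0.25 * cur, 0.8)),
      bmi = round(pmax(bmi, 15), 1)
    )
  })

  phenotypes <- data.frame(subject_id = subj, status = status, items,
                           total_ids = rowSums(items), covs,
                           stringsAsFactors = FALSE)
  rownames(phenotypes) <- NULL

  truth <- list(
    partition = partition,
    factor_scores = if (K > 0) {
      `dimnames<-`(FS[, seq_len(K), drop = FALSE],
                   list(subj, paste0("module_", seq_len(K))))
    } else NULL,
    loadings = lambda,
    planted_effects = pe,
    status_effects = se
  )

  list(proteins = protein_matrix(X, stage = "raw"),
       phenotypes = phenotypes,
       truth = truth)
}

#' Inject missingness and detection-limit censoring
#'
#' Applies per-analyte missing-completely-at-random masking at a rate
#' drawn uniformly from `config$missing_rate_range`, then places a lower
#' detection limit at each analyte's empirical `lod_censor_rate`
#' quantile: observed values below the limit are flagged censored-low
#' and replaced by the limit.
#'
#' @param proteins A complete `protein_matrix` at stage `raw` with no
#'   pre-existing missingness or censoring.
#' @param config A [sim_config()] (uses `missing_rate_range`,
#'   `lod_censor_rate`, `seed`).
#' @param missing_rates Optional numeric vector of per-analyte rates
#'   overriding the uniform draw (recycled to the analyte count).
#' @return A `protein_matrix` at stage `raw` with missing cells set to
#'   `NA`, censor flags set, and a `lod` table attached.
#' @export
inject_missingness <- function(proteins, config, missing_rates = NULL) {
  if (!inherits(proteins, "protein_matrix")) {
    stop("`proteins` must be a protein_matrix", call. = FALSE)
  }
  if (any(proteins$missing) || any(proteins$censor != "none")) {
    stop("`proteins` already carries missingness or censoring flags",
         call. = FALSE)
  }
  check_proportion(config$missing_rate_range, "missing_rate_range",
                   allow_vec = TRUE)
  check_proportion(config$lod_censor_rate, "lod_censor_rate")
  if (!is.null(missing_rates)) {
    check_proportion(missing_rates, "missing_rates", allow_vec = TRUE)
  }
  seeds <- seed_streams(config$seed, c("status", "factors", "loadings",
                                       "noise", "symptoms", "covariates",
                                       "missing", "censor"))
  X <- proteins$values
  n <- nrow(X); p <- ncol(X)
  rates <- with_seed(seeds["missing"], {
    r <- missing_rates %||%
      stats::runif(p, config$missing_rate_range[1], config$missing_rate_range[2])
    rep_len(r, p)
  })
  miss <- with_seed(seeds["missing"] + 1L, {
    m <- matrix(FALSE, n, p)
    for (jj in seq_len(p)) m[, jj] <- stats::runif(n) < rates[jj]
    m
  })

  censor <- matrix("none", n, p, dimnames = dimnames(X))
  lower <- rep(NA_real_, p)
  if (config$lod_censor_rate > 0) {
    for (jj in seq_len(p)) {
      obs <- X[!miss[, jj], jj]
      lim <- stats::quantile(obs, config$lod_censor_rate, names = FALSE)
      lower[jj] <- lim
      cl <- !miss[, jj] & X[, jj] < lim
      censor[cl, jj] <- "low"
      X[cl, jj] <- lim
    }
  }
  X[miss] <- NA_real_
  lod <- data.frame(analyte = colnames(X), lower = lower,
                    upper = NA_real_, stringsAsFactors = FALSE)
  protein_matrix(X, miss, censor, lod, stage = "raw")
}
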