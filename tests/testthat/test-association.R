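# Symptom factor construction, covariate-adjusted contrasts, Bonferroni.

mini_pheno <- function(status, items = NULL) {
  n <- length(status)
  ph <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                   status = factor(status,
                                   levels = c("control", "remitted", "current")))
  if (!is.null(items)) {
    for (j in seq_along(items)) {
      ph[[sprintf("ids_%02d", j)]] <- items[[j]]
    }
  }
  ph
}

test_that("the symptom factor splits current subjects at score >= 2", {
  ph <- mini_pheno(c("control", "remitted", "current", "current", "current"),
                   items = list(c(3L, 0L, 2L, 1L, 0L)))
  f <- build_symptom_factor(ph, 1)
  expect_identical(as.character(f),
                   c("control", "remitted", "current_high", "current_low",
                     "current_low"))
  expect_identical(levels(f),
                   c("control", "remitted", "current_low", "current_high"))
})

test_that("current subjects with missing items are dropped with a warning", {
  ph <- mini_pheno(c("control", "current", "current"),
                   items = list(c(0L, NA, 3L)))
  expect_warning(f <- build_symptom_factor(ph, 1), "1 current-status")
  expect_true(is.na(f[2]))
  expect_identical(as.character(f[3]), "current_high")
})

test_that("degenerate cohorts fail cleanly downstream", {
  ph <- mini_pheno(rep("control", 10), items = list(rep(1L, 10)))
  f <- build_symptom_factor(ph, 1)
  expect_error(fit_contrast(stats::rnorm(10), f, ph, "base",
                            "current_high_vs_control"),
               "needs groups")
  expect_error(build_symptom_factor(ph, 5), "not found")
  ph$ids_01[1] <- 7L
  expect_error(build_symptom_factor(ph, 1), "outside 0..3")
})

test_that("the covariate-free contrast equals the pooled two-sample t-test", {
  set.seed(30)
  ph <- mini_pheno(rep(c("control", "current"), c(40, 35)))
  y <- stats::rnorm(75) + 0.5 * (ph$status == "current")
  fac <- factor(ph$status, levels = c("control", "remitted", "current"))
  res <- fit_contrast(y, fac, ph, "base", "current_vs_control")
  tt <- stats::t.test(y[ph$status == "current"], y[ph$status == "control"],
                      var.equal = TRUE)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$estimate, unname(diff(rev(tt$estimate))), tolerance = 1e-10)
  expect_identical(res$n_used, 75L)
})

test_that("a covariate orthogonal to the design leaves the estimate unchanged", {
  set.seed(31)
  n <- 60
  ph <- mini_pheno(rep(c("control", "current"), each = n / 2))
  z <- stats::rnorm(n)
  # center within groups: orthogonal to intercept and group dummy
  z <- z - ave(z, ph$status)
  ph$age <- z
  y <- stats::rnorm(n) + 0.4 * (ph$status == "current")
  fac <- factor(ph$status, levels = c("control", "remitted", "current"))
  r0 <- fit_contrast(y, fac, ph[, c("subject_id", "status")], "base",
                     "current_vs_control")
  r1 <- fit_contrast(y, fac, ph, "base", "current_vs_control")
  expect_equal(r1$estimate, r0$estimate, tolerance = 1e-10)
})

test_that("rank-deficient designs error naming the aliased columns", {
  ph <- mini_pheno(rep(c("control", "current"), each = 10))
  ph$batch <- factor(rep(c("b1", "b2"), each = 10))  # confounded with group
  y <- stats::rnorm(20)
  fac <- factor(ph$status, levels = c("control", "remitted", "current"))
  expect_error(fit_contrast(y, fac, ph, "base", "current_vs_control"),
               "aliased.*batch")
})

test_that("a planted 0.4 SD effect at realistic group sizes is well powered", {
  # ~430 controls vs ~230 current-high, alpha = 0.05
  set.seed(32)
  hits <- vapply(1:200, function(i) {
    ph <- mini_pheno(rep(c("control", "current"), c(430, 230)),
                     items = list(rep(c(0L, 3L), c(430, 230))))
    f <- build_symptom_factor(ph, 1)
    y <- stats::rnorm(660) + 0.4 * (f == "current_high")
    fit_contrast(y, f, ph, "base", "current_high_vs_control")$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Bonferroni adjustment multiplies and clips", {
  expect_equal(bonferroni_adjust(9.62e-3, 6), 0.05772)
  expect_equal(bonferroni_adjust(1.0, 12), 1.0)
  expect_equal(bonferroni_adjust(0.2, 10), 1.0)
  expect_equal(bonferroni_adjust(0.001, 28), 0.028)
  expect_error(bonferroni_adjust(1.2, 3), "p")
  # monotone in the multiplier, never below nominal
  p <- c(0.001, 0.04, 0.6)
  for (m in c(1L, 3L, 10L)) {
    expect_true(all(bonferroni_adjust(p, m) >= p))
  }
  expect_true(all(bonferroni_adjust(p, 6) >= bonferroni_adjust(p, 2)))
})

test_that("status scan uses the module count as multiplier and flags min p", {
  cfg <- sim_config(n_subjects = 400, n_analytes = 30,
                    module_spec = mspec(c(9, 8)),
                    missing_rate_range = c(0, 0), lod_censor_rate = 0,
                    status_effects = data.frame(module = 1, remitted = 0,
                                                current = 0.8),
                    planted_effects = data.frame(module = integer(),
                                                 symptom = integer(),
                                                 effect = numeric()),
                    bmi_coupling = 0, seed = 33)
  ch <- simulate_cohort(cfg)
  pm <- inverse_normal_transform(impute_matrix(ch$proteins))
  part <- cluster_matrix(pm)
  eps <- eigenprotein_set(pm, part)
  scan <- scan_clusters_vs_status(eps, ch$phenotypes, "base")
  expect_identical(unique(scan$multiplier), nrow(scan))
  expect_equal(scan$p_bonferroni, pmin(1, scan$p * nrow(scan)))
  expect_identical(sum(scan$selected), 1L)
  # the planted-status module must be the selected one
  sel_members <- names(part$assignment)[part$assignment ==
    as.integer(sub("EP", "", scan$module[scan$selected]))]
  expect_gt(mean(sel_members %in%
                   names(ch$truth$partition)[ch$truth$partition == 1]), 0.8)
  # single module: adjusted equals nominal
  one <- scan_clusters_vs_status(eps$scores[, 1, drop = FALSE],
                                 ch$phenotypes, "base")
  expect_equal(one$p_bonferroni, min(1, one$p))
})

test_that("BMI-tier adjustment attenuates a BMI-coupled module effect", {
  diffs <- vapply(1:3, function(s) {
    cfg <- sim_config(n_subjects = 800, n_analytes = 24,
                      module_spec = mspec(c(8, 8)),
                      missing_rate_range = c(0, 0), lod_censor_rate = 0,
                      planted_effects = data.frame(module = integer(),
                                                   symptom = integer(),
                                                   effect = numeric()),
                      status_effects = data.frame(module = 2, remitted = 0.1,
                                                  current = 0.5),
                      bmi_coupling = 3, seed = 40 + s)
    ch <- simulate_cohort(cfg)
    pm <- inverse_normal_transform(impute_matrix(ch$proteins))
    ep <- eigenprotein(pm, names(ch$truth$partition)[ch$truth$partition == 2])
    fac <- factor(ch$phenotypes$status,
                  levels = c("control", "remitted", "current"))
    base <- fit_contrast(ep$scores, fac, ch$phenotypes, "base",
                         "current_vs_control")
    bmi <- fit_contrast(ep$scores, fac, ch$phenotypes, "bmi",
                        "current_vs_control")
    expect_identical(sign(bmi$estimate), sign(base$estimate))
    base$estimate - bmi$estimate
  }, numeric(1))
  expect_gt(mean(diffs), 0)   # shrinkage toward zero on average
})

test_that("symptom scan multiplier is items x modules and sorts by p", {
  cfg <- sim_config(n_subjects = 1000, n_analytes = 12, module_spec = mspec(8),
                    missing_rate_range = c(0, 0), lod_censor_rate = 0,
                    planted_effects = data.frame(module = 1, symptom = 5,
                                                 effect = 2),
                    status_effects = data.frame(module = integer(),
                                                remitted = numeric(),
                                                current = numeric()),
                    bmi_coupling = 0, seed = 50)
  ch <- simulate_cohort(cfg)
  pm <- inverse_normal_transform(impute_matrix(ch$proteins))
  ep <- eigenprotein(pm, names(ch$truth$partition)[ch$truth$partition == 1])
  S <- matrix(ep$scores, ncol = 1, dimnames = list(NULL, "EP1"))
  res <- scan_symptoms(S, ch$phenotypes, "base", "current_high_vs_control",
                       symptom_items = 1:10)
  expect_identical(nrow(res), 10L)
  expect_identical(unique(res$multiplier), 10L)
  expect_false(is.unsorted(res$p))
  expect_identical(res$item[1], "ids_05")
})
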