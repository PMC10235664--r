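# Unsigned network construction, module detection, eigenproteins, kME.

test_that("correlation matrix matches the direct covariance formula", {
  set.seed(4)
  X <- matrix(stats::rnorm(15), 5, 3,
              dimnames = list(sprintf("S%03d", 1:5), c("a", "b", "c")))
  R <- correlation_matrix(as_pm(X))
  brute <- matrix(1, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    brute[i, j] <- sum((X[, i] - mean(X[, i])) * (X[, j] - mean(X[, j]))) /
      sqrt(sum((X[, i] - mean(X[, i]))^2) * sum((X[, j] - mean(X[, j]))^2))
  }
  expect_equal(unname(R), brute, tolerance = 1e-12)
  # identical and negated columns
  Y <- cbind(X, d = X[, 1], e = -X[, 1])
  RY <- correlation_matrix(as_pm(Y))
  expect_equal(RY["a", "d"], 1, tolerance = 1e-12)
  expect_equal(RY["a", "e"], -1, tolerance = 1e-12)
})

test_that("soft thresholding is unsigned with correct boundary values", {
  R <- matrix(c(1, 0.5, -0.5, 0,
                0.5, 1, 1, -1,
                -0.5, 1, 1, 0,
                0, -1, 0, 1), 4, 4)
  R <- (R + t(R)) / 2
  A <- soft_threshold_adjacency(R, network_config(beta = 4))
  expect_equal(A[1, 2], 0.0625)
  expect_equal(A[1, 3], 0.0625)   # sign ignored
  expect_equal(A[1, 4], 0)
  expect_equal(A[2, 4], 1)
  expect_true(all(A >= 0 & A <= 1))
  expect_equal(diag(A), rep(1, 4))
})

test_that("scale-free fit recovers an exact power law and flags degeneracy", {
  # construct connectivities whose frequencies follow k^-1: freq = 64/k
  k_vals <- 2^(0:5)
  freq <- 64 / k_vals
  k <- rep(k_vals, times = freq)
  fit <- scale_free_fit(k, n_bins = 32L)
  expect_gte(fit$r_squared, 0.999)
  expect_equal(fit$slope, -1, tolerance = 0.01)
  # complete graph with equal weights: single connectivity value
  A <- matrix(0.5, 6, 6); diag(A) <- 1
  expect_error(scale_free_fit(A), "single bin|non-empty")
  # permutation invariance on a random adjacency
  set.seed(6)
  B <- matrix(stats::runif(100), 10, 10); B <- (B + t(B)) / 2; diag(B) <- 1
  perm <- sample(10)
  expect_equal(scale_free_fit(B)$r_squared,
               scale_free_fit(B[perm, perm])$r_squared, tolerance = 1e-12)
})

test_that("topological overlap matches hand-computed and brute-force values", {
  # three mutually connected nodes with unit weights: perfect overlap
  A1 <- matrix(1, 3, 3)
  expect_equal(topological_overlap(A1)[1, 2], 1)
  # single connected pair: TOM = (0 + 0.5)/(0.5 + 1 - 0.5)
  A2 <- diag(3)
  A2[1, 2] <- A2[2, 1] <- 0.5
  expect_equal(topological_overlap(A2)[1, 2], 0.5)
  expect_equal(topological_overlap(A2)[1, 3], 0)
  # random adjacency vs triple-loop oracle
  set.seed(8)
  B <- matrix(stats::runif(36), 6, 6)
  B <- (B + t(B)) / 2
  diag(B) <- 1
  T1 <- topological_overlap(B)
  expect_equal(unname(T1), tom_brute(B), tolerance = 1e-12)
  expect_true(all(T1 >= 0 & T1 <= 1 + 1e-12))
  expect_equal(T1, t(T1))
})

test_that("planted blocks are recovered exactly at zero noise", {
  bl <- make_blocks(200, c(10, 8), loading = 1, noise = 0,
                    n_background = 12, seed = 10)
  part <- cluster_matrix(as_pm(bl$X))
  expect_identical(length(part$module_sizes), 2L)
  expect_equal(adjusted_rand(part$assignment, bl$truth), 1)
  expect_true(all(part$assignment[bl$truth == 0] == 0))
  # labels ordered by decreasing size
  expect_identical(part$module_sizes, c(10L, 8L))
})

test_that("independent analytes yield zero modules", {
  for (s in 1:3) {
    bl <- make_blocks(800, integer(0), 0.5, 1, n_background = 40, seed = s)
    pm <- inverse_normal_transform(impute_matrix(as_pm(bl$X, stage = "raw")))
    part <- cluster_matrix(pm)
    expect_identical(length(part$module_sizes), 0L)
    expect_true(all(part$assignment == 0))
  }
})

test_that("blocks below the minimum module size are not returned", {
  bl <- make_blocks(300, 4, loading = 1, noise = 0, n_background = 20,
                    seed = 12)
  part <- cluster_matrix(as_pm(bl$X),
                         network_config(min_module_size = 5))
  expect_true(all(part$assignment[bl$truth == 1] == 0))
})

test_that("partition is invariant to analyte order up to relabeling", {
  bl <- make_blocks(400, c(9, 7), 0.55, 1, n_background = 10, seed = 14)
  pm <- inverse_normal_transform(impute_matrix(as_pm(bl$X, stage = "raw")))
  part1 <- cluster_matrix(pm)
  set.seed(15)
  perm <- sample(ncol(bl$X))
  pm2 <- protein_matrix(pm$values[, perm], stage = "transformed")
  part2 <- cluster_matrix(pm2)
  expect_equal(adjusted_rand(part1$assignment[perm], part2$assignment), 1)
})

test_that("eigenprotein handles rank-1 and sign-structured modules", {
  set.seed(16)
  x <- stats::rnorm(50)
  X <- cbind(a = x, b = x)
  rownames(X) <- sprintf("S%03d", 1:50)
  ep <- eigenprotein(X, c("a", "b"))
  expect_equal(ep$variance_explained, 1, tolerance = 1e-12)
  expect_equal(abs(stats::cor(ep$scores, x)), 1, tolerance = 1e-12)
  expect_equal(mean(ep$scores), 0, tolerance = 1e-12)
  expect_equal(stats::sd(ep$scores), 1, tolerance = 1e-12)
  # sign-structured module: variance explained 1, kME +/- 1, and the
  # majority-positive orientation puts +1 on the majority sign
  Y <- cbind(a = x, b = x, c = x, d = -x, e = -x)
  rownames(Y) <- rownames(X)
  epy <- eigenprotein(Y, colnames(Y))
  expect_equal(epy$variance_explained, 1, tolerance = 1e-12)
  kme <- module_membership(Y, matrix(epy$scores, ncol = 1,
                                     dimnames = list(NULL, "EP1")))
  expect_equal(kme$kme, c(1, 1, 1, -1, -1), tolerance = 1e-10)
  expect_gt(mean(stats::cor(epy$scores, Y)), 0)
  expect_error(eigenprotein(X, "a"), ">= 2")
})

test_that("eigenprotein agrees with a dense eigendecomposition oracle", {
  set.seed(18)
  bl <- make_blocks(120, 8, 0.6, 1, 0, seed = 18)
  ep <- eigenprotein(bl$X, colnames(bl$X))
  ev <- eigen(stats::cor(bl$X))
  oracle <- scale(bl$X) %*% ev$vectors[, 1]
  expect_equal(abs(stats::cor(ep$scores, oracle[, 1])), 1, tolerance = 1e-10)
  expect_equal(ep$variance_explained, ev$values[1] / sum(ev$values),
               tolerance = 1e-10)
})

test_that("kME p-values match the t-distribution formula and are calibrated", {
  set.seed(20)
  n <- 200
  X <- matrix(stats::rnorm(n * 3), n, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  S <- matrix(stats::rnorm(n), n, 1, dimnames = list(NULL, "EP1"))
  km <- module_membership(X, S)
  for (i in 1:3) {
    r <- stats::cor(X[, i], S[, 1])
    tval <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(km$p_value[i], 2 * stats::pt(-abs(tval), n - 2),
                 tolerance = 1e-10)
  }
  # analyte identical to the scores
  km2 <- module_membership(cbind(a = S[, 1]), S)
  expect_equal(km2$kme, 1, tolerance = 1e-12)
  expect_lt(km2$p_value, 1e-100)
  # null calibration: p uniform across 500 independent simulations
  set.seed(21)
  pvals <- vapply(1:500, function(i) {
    x <- matrix(stats::rnorm(100), 100, 1, dimnames = list(NULL, "a"))
    s <- matrix(stats::rnorm(100), 100, 1, dimnames = list(NULL, "EP1"))
    module_membership(x, s)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("mean absolute within-module correlation averages distinct pairs", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.3
  R[1, 3] <- R[3, 1] <- -0.3
  R[2, 3] <- R[3, 2] <- 0.6
  dimnames(R) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(mean_abs_within_correlation(R, c("a", "b", "c")), 0.4)
  # identical columns give 1
  set.seed(22)
  x <- stats::rnorm(30)
  X <- cbind(a = x, b = x, c = x); rownames(X) <- sprintf("S%03d", 1:30)
  expect_equal(mean_abs_within_correlation(stats::cor(X), c("a", "b", "c")), 1)
  expect_error(mean_abs_within_correlation(R, "a"), ">= 2")
})
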