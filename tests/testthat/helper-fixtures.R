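# Fixture builders and independent oracles shared across test files.

# wrap a bare matrix as a protein_matrix at a given stage
as_pm <- function(X, stage = "transformed") {
  if (is.null(rownames(X))) rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("prot_%03d", seq_len(ncol(X)))
  protein_matrix(X, stage = stage)
}

# minimal factor-model block generator, independent of simulate_cohort(),
# used as the fixture source for network-level oracle tests
make_blocks <- function(n, sizes, loading, noise, n_background, seed) {
  set.seed(seed)
  p <- sum(sizes) + n_background
  X <- matrix(stats::rnorm(n * p, sd = noise), n, p)
  truth <- integer(p)
  j <- 0L
  for (m in seq_along(sizes)) {
    f <- stats::rnorm(n)
    for (s in seq_len(sizes[m])) {
      j <- j + 1L
      X[, j] <- loading * f + X[, j]
      truth[j] <- m
    }
  }
  if (n_background > 0) {
    X[, (j + 1L):p] <- stats::rnorm(n * n_background)
  }
  dimnames(X) <- list(sprintf("S%04d", seq_len(n)),
                      sprintf("prot_%03d", seq_len(p)))
  list(X = X, truth = truth)
}

# brute-force topological overlap by triple loop
tom_brute <- function(A) {
  diag(A) <- 0
  p <- nrow(A)
  k <- rowSums(A)
  TOM <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) { TOM[i, j] <- 1; next }
      L <- 0
      for (u in seq_len(p)) if (u != i && u != j) L <- L + A[i, u] * A[u, j]
      TOM[i, j] <- (L + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
  }
  TOM
}

# sim_config shorthand with effects and missingness switched off
quiet_sim_config <- function(n_subjects, module_spec, n_analytes,
                             noise_sd = 1, seed = 1, ...) {
  sim_config(
    n_subjects = n_subjects, n_analytes = n_analytes,
    module_spec = module_spec, noise_sd = noise_sd,
    missing_rate_range = c(0, 0), lod_censor_rate = 0,
    planted_effects = data.frame(module = integer(), symptom = integer(),
                                 effect = numeric()),
    status_effects = data.frame(module = integer(), remitted = numeric(),
                                current = numeric()),
    bmi_coupling = 0, seed = seed, ...)
}

mspec <- function(sizes, loading = 0.55, frac_neg = 0) {
  data.frame(size = as.integer(sizes),
             loading_mean = rep_len(loading, length(sizes)),
             frac_negative = rep_len(frac_neg, length(sizes)))
}

# full network path: transformed matrix -> module partition
cluster_matrix <- function(pm, config = network_config()) {
  A <- soft_threshold_adjacency(correlation_matrix(pm), config)
  D <- if (config$dissimilarity == "tom") 1 - topological_overlap(A) else 1 - A
  diag(D) <- 0
  detect_modules(D, config)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
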