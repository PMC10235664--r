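# Unsigned weighted correlation network: soft-thresholded adjacency,
# scale-free fit diagnostics, topological overlap, average-linkage
# clustering with adaptive dendrogram-shape branch pruning, eigenproteins
# and module membership (kME).

#' Pearson correlation matrix of a transformed protein matrix
#'
#' @param proteins A `protein_matrix` at stage `transformed` (or a bare
#'   numeric matrix with column names).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(proteins) {
  X <- if (inherits(proteins, "protein_matrix")) {
    if (proteins$stage != "transformed") {
      stop("expected stage `transformed`", call. = FALSE)
    }
    proteins$values
  } else proteins
  if (anyNA(X)) stop("matrix contains missing cells", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance analyte(s): %s",
                 paste(colnames(X)[sds == 0], collapse = ", ")),
         call. = FALSE)
  }
  R <- stats::cor(X)
  diag(R) <- 1
  R
}

#' Soft-thresholded unsigned adjacency
#'
#' Connection strength a_ij = |r_ij|^beta: the absolute correlation
#' (unsigned network) raised to the soft-threshold power.
#'
#' @param cor_mat Symmetric correlation matrix.
#' @param config A [network_config()]; `beta` defaults to 4.
#' @return Adjacency matrix with entries in [0, 1] and unit diagonal.
#' @export
soft_threshold_adjacency <- function(cor_mat, config = network_config()) {
  check_square_sym(cor_mat, "cor_mat")
  if (any(abs(cor_mat) > 1 + 1e-8)) {
    stop("`cor_mat` entries must lie in [-1, 1]", call. = FALSE)
  }
  A <- abs(cor_mat)^config$beta
  diag(A) <- 1
  A
}

#' Network connectivity
#'
#' Per-node connectivity k_i = sum over j != i of a_ij.
#'
#' @param adjacency Adjacency matrix.
#' @return Numeric vector of connectivities.
#' @export
connectivity <- function(adjacency) {
  check_square_sym(adjacency, "adjacency")
  rowSums(adjacency) - diag(adjacency)
}

#' Scale-free topology fit
#'
#' Bins the connectivity distribution into equal-width bins, then
#' regresses log10(frequency) on log10(mean connectivity per bin). The
#' R-squared and slope report (not enforce) how closely the network at
#' the configured soft-threshold power approaches scale-free topology.
#'
#' @param adjacency Adjacency matrix, or a precomputed connectivity
#'   vector.
#' @param n_bins Number of connectivity bins (default 10).
#' @return A list with `r_squared`, `slope`, `n_bins_used` and the
#'   per-bin table.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10L) {
  k <- if (is.matrix(adjacency)) connectivity(adjacency) else as.numeric(adjacency)
  check_count(n_bins, "n_bins", min = 2L)
  if (max(k) == min(k)) {
    stop("degenerate connectivity distribution: single bin", call. = FALSE)
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  kmean <- vapply(seq_len(n_bins), function(b) {
    if (freq[b] > 0) mean(k[as.integer(bin) == b]) else NA_real_
  }, numeric(1))
  keep <- freq > 0 & kmean > 0
  if (sum(keep) < 3L) {
    stop("fewer than 3 non-empty connectivity bins", call. = FALSE)
  }
  df <- data.frame(k_mean = kmean[keep], frequency = freq[keep])
  fit <- stats::lm(log10(frequency) ~ log10(k_mean), data = df)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       n_bins_used = sum(keep),
       bins = df)
}

#' Topological overlap matrix (unsigned)
#'
#' TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij), where
#' L_ij = sum_u a_iu a_uj over u != i, j and k is connectivity. The
#' overlap augments the direct connection strength with shared
#' neighbourhood strength; 1 - TOM is the clustering dissimilarity.
#'
#' @param adjacency Symmetric adjacency with entries in [0, 1].
#' @return Symmetric TOM matrix, entries in [0, 1], unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  check_square_sym(adjacency, "adjacency")
  if (any(adjacency < -1e-12) || any(adjacency > 1 + 1e-12)) {
    stop("`adjacency` entries must lie in [0, 1]", call. = FALSE)
  }
  A <- adjacency
  diag(A) <- 0
  L <- A %*% A
  k <- rowSums(A)
  kmin <- outer(k, k, pmin)
  TOM <- (L + A) / (kmin + 1 - A)
  diag(TOM) <- 1
  dimnames(TOM) <- dimnames(adjacency)
  TOM
}

#' Detect modules by adaptive branch pruning of the dendrogram
#'
#' Builds an average-linkage dendrogram of the dissimilarity matrix and
#' decomposes it into branches by dendrogram shape: a branch qualifies
#' as a module when (i) it contains at least `min_module_size`
#' analytes, (ii) its core merges sit low relative to the spread of
#' merge heights (tight core), and (iii) it attaches to the rest of the
#' tree well above its own top merge (clear gap). Both thresholds are
#' expressed relative to the range between the 5th height percentile
#' and the maximum height and are controlled by `deep_split`. Maximal
#' qualifying branches become modules; analytes in no qualifying branch
#' are left unassigned (label 0). Labels are 1..K by decreasing size.
#'
#' @param dissimilarity Square symmetric dissimilarity matrix with zero
#'   diagonal, typically `1 - topological_overlap(adjacency)`.
#' @param config A [network_config()].
#' @return A `module_partition`: list with `assignment` (named integer
#'   vector, 0 = unassigned), `module_sizes`, and `dendrogram` (the
#'   `hclust` object).
#' @export
detect_modules <- function(dissimilarity, config = network_config()) {
  check_square_sym(dissimilarity, "dissimilarity")
  if (any(abs(diag(dissimilarity)) > 1e-8)) {
    stop("`dissimilarity` must have zero diagonal", call. = FALSE)
  }
  n <- nrow(dissimilarity)
  ids <- colnames(dissimilarity) %||% paste0("V", seq_len(n))
  if (n < config$min_module_size) {
    warning("fewer analytes than min_module_size: all unassigned")
    return(new_module_partition(stats::setNames(integer(n), ids), NULL))
  }
  hc <- stats::hclust(stats::as.dist(dissimilarity), method = "average")
  labels0 <- cut_branches(hc, config$min_module_size, config$deep_split)
  new_module_partition(stats::setNames(labels0, ids), hc)
}

new_module_partition <- function(assignment, dendrogram) {
  sizes <- if (max(assignment) > 0) {
    tabulate(assignment[assignment > 0])
  } else integer(0)
  structure(list(assignment = assignment,
                 module_sizes = sizes,
                 dendrogram = dendrogram),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  k <- length(x$module_sizes)
  cat(sprintf("<module_partition> %d analytes, %d module(s), %d unassigned\n",
              length(x$assignment), k, sum(x$assignment == 0)))
  if (k > 0) cat("  sizes:", paste(x$module_sizes, collapse = ", "), "\n")
  invisible(x)
}

# --- adaptive branch pruning -------------------------------------------------

# Per-internal-node statistics of an hclust tree: subtree size, leaves,
# internal merge heights, and parent index.
tree_node_stats <- function(hc) {
  nh <- length(hc$height)
  sizes <- integer(nh)
  subh <- vector("list", nh)
  leaves <- vector("list", nh)
  parent <- rep(NA_integer_, nh)
  for (i in seq_len(nh)) {
    lv <- integer(0); hs <- hc$height[i]
    for (ch in hc$merge[i, ]) {
      if (ch < 0) {
        lv <- c(lv, -ch)
      } else {
        lv <- c(lv, leaves[[ch]])
        hs <- c(hs, subh[[ch]])
        parent[ch] <- i
      }
    }
    leaves[[i]] <- lv; subh[[i]] <- hs; sizes[i] <- length(lv)
  }
  list(sizes = sizes, subh = subh, leaves = leaves, parent = parent)
}

# Decompose an average-linkage dendrogram into branch modules.
# deep_split (0..4) maps to a core-tightness fraction and a gap fraction
# of the height range between the 5th percentile and the maximum.
cut_branches <- function(hc, min_size, deep_split) {
  n <- length(hc$height) + 1L
  H <- hc$height
  lab <- integer(n)
  h5 <- unname(stats::quantile(H, 0.05))
  hmax <- max(H)
  R <- hmax - h5
  if (R < 1e-12) {
    # all merges at one height: a single undifferentiated cluster
    if (n >= min_size) lab[] <- 1L
    return(lab)
  }
  mcs <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1L]
  gapf <- (1 - mcs) * 3 / 4
  st <- tree_node_stats(hc)
  qual <- logical(n - 1L)
  for (i in seq_len(n - 1L)) {
    if (st$sizes[i] < min_size || is.na(st$parent[i])) next
    gap <- H[st$parent[i]] - H[i]
    hs <- st$subh[[i]]
    core <- mean(sort(hs)[seq_len(min(min_size - 1L, length(hs)))])
    qual[i] <- core <= h5 + mcs * R && gap >= gapf * R
  }
  # maximal qualifying branches, found top-down from the root
  modules <- list()
  stack <- n - 1L
  while (length(stack)) {
    i <- stack[[1L]]; stack <- stack[-1L]
    if (i < 0) next
    if (qual[i]) {
      modules[[length(modules) + 1L]] <- st$leaves[[i]]
    } else {
      stack <- c(stack, hc$merge[i, 1L], hc$merge[i, 2L])
    }
  }
  if (length(modules)) {
    # label 1..K by decreasing size; ties by lowest first leaf index
    sz <- vapply(modules, length, integer(1))
    first <- vapply(modules, min, integer(1))
    ord <- order(-sz, first)
    for (k in seq_along(ord)) lab[modules[[ord[k]]]] <- k
  }
  lab
}

# --- eigenproteins and module membership -------------------------------------

#' Eigenprotein of one module
#'
#' The first principal component of the standardized module submatrix,
#' rescaled to mean 0 / SD 1 and signed so that its mean correlation
#' with the module's analytes is positive: a weighted average level of
#' the module.
#'
#' @param proteins A `protein_matrix` at stage `transformed` (or a bare
#'   numeric matrix).
#' @param module Character vector of analyte identifiers (size >= 2).
#' @return A list with `scores` (length n, mean 0, SD 1) and
#'   `variance_explained` (leading eigenvalue share in (0, 1]).
#' @export
eigenprotein <- function(proteins, module) {
  X <- if (inherits(proteins, "protein_matrix")) proteins$values else proteins
  if (length(module) < 2L) stop("module must contain >= 2 analytes",
                                call. = FALSE)
  if (!all(module %in% colnames(X))) {
    stop("unknown analytes in module", call. = FALSE)
  }
  M <- scale(X[, module, drop = FALSE])
  sv <- svd(M, nu = 1, nv = 0)
  scores <- sv$u[, 1]
  scores <- scores / stats::sd(scores)
  scores <- scores - mean(scores)
  if (mean(stats::cor(scores, M)) < 0) scores <- -scores
  list(scores = stats::setNames(scores, rownames(X)),
       variance_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Eigenproteins for every module of a partition
#'
#' @param proteins A `protein_matrix` at stage `transformed`.
#' @param partition A `module_partition`.
#' @return An `eigenprotein_set`: list with `scores` (subjects x
#'   modules, columns `EP1..EPK`), `variance_explained`, and `kme`
#'   (module membership table from [module_membership()]).
#' @export
eigenprotein_set <- function(proteins, partition) {
  asg <- partition$assignment
  K <- max(asg)
  if (K < 1) stop("partition contains no modules", call. = FALSE)
  X <- proteins$values
  scores <- matrix(NA_real_, nrow(X), K,
                   dimnames = list(rownames(X), paste0("EP", seq_len(K))))
  ve <- stats::setNames(numeric(K), paste0("EP", seq_len(K)))
  for (m in seq_len(K)) {
    ep <- eigenprotein(proteins, names(asg)[asg == m])
    scores[, m] <- ep$scores
    ve[m] <- ep$variance_explained
  }
  out <- structure(list(scores = scores, variance_explained = ve,
                        kme = NULL, partition = partition),
                   class = "eigenprotein_set")
  out$kme <- module_membership(proteins, out)
  out
}

#' @export
print.eigenprotein_set <- function(x, ...) {
  cat(sprintf("<eigenprotein_set> %d subjects x %d modules\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  variance explained:",
      paste(sprintf("%.2f", x$variance_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Module membership (kME)
#'
#' Pearson correlation of each analyte with each module eigenprotein,
#' with the two-sided p-value from the t distribution on n - 2 degrees
#' of freedom.
#'
#' @param proteins A `protein_matrix` at stage `transformed` (or a bare
#'   numeric matrix).
#' @param eigenproteins An `eigenprotein_set`, or a bare scores matrix.
#' @return Data frame with one row per analyte x module: `analyte`,
#'   `module`, `kme`, `p_value`.
#' @export
module_membership <- function(proteins, eigenproteins) {
  X <- if (inherits(proteins, "protein_matrix")) proteins$values else proteins
  S <- if (inherits(eigenproteins, "eigenprotein_set")) {
    eigenproteins$scores
  } else eigenproteins
  n <- nrow(X)
  r <- stats::cor(X, S)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(
    analyte = rep(colnames(X), times = ncol(S)),
    module = rep(colnames(S), each = ncol(X)),
    kme = as.vector(r),
    p_value = as.vector(p),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Mean absolute within-module correlation
#'
#' Mean of |r_ij| over unordered distinct analyte pairs in a module.
#'
#' @param cor_mat Correlation matrix over all analytes.
#' @param module Character vector of analyte identifiers (size >= 2).
#' @return Scalar mean absolute correlation.
#' @export
mean_abs_within_correlation <- function(cor_mat, module) {
  if (length(module) < 2L) stop("module must contain >= 2 analytes",
                                call. = FALSE)
  sub <- abs(cor_mat[module, module, drop = FALSE])
  mean(sub[upper.tri(sub)])
}

check_square_sym <- function(M, field) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    stop_bad(field, "must be a square matrix")
  }
  if (max(abs(M - t(M))) > 1e-8) stop_bad(field, "must be symmetric")
  invisible(M)
}
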