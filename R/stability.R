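# Split-half resampling assessment of a reference module: the cohort is
# repeatedly halved, each half is re-clustered with the main run's
# network settings, and the module best overlapping the reference is
# tracked per half.

#' Split subjects into two random halves
#'
#' Disjoint, exhaustive halves of sizes ceiling(n/2) and floor(n/2)
#' (1621 subjects split as 811 and 810), uniformly random given the
#' seed.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param seed Integer seed.
#' @return List with integer index vectors `a` and `b`.
#' @export
split_half <- function(n_subjects, seed) {
  check_count(n_subjects, "n_subjects", min = 4L)
  check_count(seed, "seed")
  na <- ceiling(n_subjects / 2)
  a <- with_seed(seed, sort(sample.int(n_subjects, na)))
  list(a = a, b = setdiff(seq_len(n_subjects), a))
}

#' Module with most overlap with a reference analyte set
#'
#' Over the non-zero modules of a partition, finds the module with the
#' largest intersection with the reference. Ties are broken toward the
#' smaller module (higher precision), then toward the lower label.
#'
#' @param reference Character vector of analyte identifiers.
#' @param partition A `module_partition` over the same analyte universe.
#' @return List with `module` (label, or `NA` if no module overlaps),
#'   `overlap` (count) and `size` (best module's size, 0 if none).
#' @export
best_overlap <- function(reference, partition) {
  asg <- partition$assignment
  if (!all(reference %in% names(asg))) {
    stop("reference analytes missing from the partition's universe",
         call. = FALSE)
  }
  K <- max(asg)
  if (K < 1) return(list(module = NA_integer_, overlap = 0L, size = 0L))
  ov <- vapply(seq_len(K), function(m) {
    sum(names(asg)[asg == m] %in% reference)
  }, integer(1))
  sz <- partition$module_sizes
  if (all(ov == 0L)) return(list(module = NA_integer_, overlap = 0L, size = 0L))
  best <- order(-ov, sz, seq_len(K))[1]
  list(module = best, overlap = ov[best], size = sz[best])
}

#' Split-half stability of a reference module
#'
#' For each iteration the cohort is split into two random halves; each
#' half is inverse-normal transformed afresh (ranks are sample
#' relative), re-clustered with the configured network settings, and
#' the module best overlapping the reference is recorded. Per-analyte
#' inclusion frequency is the share of the 2 x iterations half-sample
#' clusterings whose best-overlap module contained the analyte.
#'
#' @param proteins A `protein_matrix` at stage `imputed` (the
#'   full-sample imputed matrix; the transform is re-applied within
#'   each half).
#' @param config A [stability_config()].
#' @return A `stability_report`: per-record table (`iteration`, `half`,
#'   `module`, `size`, `overlap`), summary (mean/SD of size and
#'   overlap), per-analyte `frequency`, and the failure count.
#' @export
run_stability <- function(proteins, config) {
  if (!inherits(config, "stability_config")) {
    stop("`config` must be a stability_config", call. = FALSE)
  }
  if (proteins$stage == "raw") {
    stop("expected an imputed protein_matrix", call. = FALSE)
  }
  ref <- config$reference_module
  if (!all(ref %in% analyte_ids(proteins))) {
    stop("reference module analytes missing from the matrix", call. = FALSE)
  }
  it <- config$iterations
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max - 1L, it))
  n <- nrow(proteins$values)
  ids <- analyte_ids(proteins)
  incl <- stats::setNames(integer(length(ids)), ids)
  recs <- vector("list", 2L * it)
  failures <- 0L
  for (i in seq_len(it)) {
    sp <- split_half(n, seeds[i])
    for (h in 1:2) {
      idx <- if (h == 1) sp$a else sp$b
      rec <- tryCatch({
        half <- subset_subjects(proteins, idx)
        half <- inverse_normal_transform(half)
        R <- correlation_matrix(half)
        A <- soft_threshold_adjacency(R, config$network)
        D <- if (config$network$dissimilarity == "tom") {
          1 - topological_overlap(A)
        } else 1 - A
        diag(D) <- 0
        part <- detect_modules(D, config$network)
        bo <- best_overlap(ref, part)
        if (!is.na(bo$module)) {
          mem <- names(part$assignment)[part$assignment == bo$module]
          incl[mem] <- incl[mem] + 1L
        }
        data.frame(iteration = i, half = h, module = bo$module,
                   size = bo$size, overlap = bo$overlap, failed = FALSE)
      }, error = function(e) {
        data.frame(iteration = i, half = h, module = NA_integer_,
                   size = NA_integer_, overlap = NA_integer_, failed = TRUE)
      })
      recs[[2L * (i - 1L) + h]] <- rec
    }
  }
  records <- do.call(rbind, recs)
  failures <- sum(records$failed)
  if (failures > 0.10 * nrow(records)) {
    stop(sprintf("%d of %d half-sample clusterings failed (> 10%%)",
                 failures, nrow(records)), call. = FALSE)
  }
  ok <- records[!records$failed, , drop = FALSE]
  summary <- list(
    mean_size = mean(ok$size), sd_size = stats::sd(ok$size),
    mean_overlap = mean(ok$overlap), sd_overlap = stats::sd(ok$overlap),
    n_records = nrow(records), n_failed = failures
  )
  structure(list(records = records, summary = summary,
                 frequency = incl / (2 * it),
                 reference_module = ref),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<stability_report> %d half-sample clusterings (%d failed)\n",
    s$n_records, s$n_failed))
  cat(sprintf("  best-overlap size:    %.1f (sd %.1f)\n",
              s$mean_size, s$sd_size))
  cat(sprintf("  overlap w/ reference: %.1f (sd %.1f) of %d\n",
              s$mean_overlap, s$sd_overlap, length(x$reference_module)))
  invisible(x)
}
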