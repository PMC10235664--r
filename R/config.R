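#' Default module specification for the synthetic panel
#'
#' Six blocks of intercorrelated analytes sized 24, 21, 13, 10, 7 and 6
#' (81 analytes in blocks, the remaining 90 of a 171-analyte panel are
#' unstructured background). The second block carries a slightly higher
#' loading (0.60, giving an expected mean within-block absolute
#' correlation near 0.26 at unit noise) and a minority of sign-flipped
#' loadings (4 of 21), emulating a serum immuno-metabolic cluster in
#' which a few analytes (e.g. adiponectin-like markers) run against the
#' rest of the block.
#'
#' @return A data frame with columns `size`, `loading_mean`,
#'   `frac_negative`.
#' @export
default_module_spec <- function() {
  data.frame(
    size          = c(24L, 21L, 13L, 10L, 7L, 6L),
    loading_mean  = c(0.55, 0.60, 0.55, 0.55, 0.55, 0.55),
    frac_negative = c(0, 4 / 21, 0, 0, 0, 0)
  )
}

#' Default planted symptom effects
#'
#' Five designated "energy-related" symptom items (positions 3, 12, 14,
#' 20 and 24 of the 30-item ordinal questionnaire; item identities are
#' positional placeholders in the synthetic cohort) load on the second
#' module's latent factor with an ordered-logit slope of 1 per factor
#' standard deviation.
#'
#' @return A data frame with columns `module`, `symptom`, `effect`.
#' @export
default_planted_effects <- function() {
  data.frame(
    module  = 2L,
    symptom = c(3L, 12L, 14L, 20L, 24L),
    effect  = 1.0
  )
}

#' Simulation configuration for the synthetic cohort generator
#'
#' @param n_subjects Number of subjects (default 1621, split roughly
#'   426/483/712 across control/remitted/current by `prevalence`).
#' @param n_analytes Total analytes on the panel; analytes beyond the
#'   blocks in `module_spec` are independent background noise.
#' @param module_spec Data frame with columns `size`, `loading_mean`
#'   (in (0, 1]) and `frac_negative` (proportion of sign-flipped
#'   loadings) describing the correlated blocks.
#' @param noise_sd Standard deviation of per-analyte noise around the
#'   latent factor contribution.
#' @param missing_rate_range Length-2 range; each analyte's MCAR missing
#'   rate is drawn uniformly from it.
#' @param lod_censor_rate Proportion of each analyte's distribution
#'   below its lower detection limit (the limit is placed at this
#'   empirical quantile).
#' @param planted_effects Data frame (`module`, `symptom`, `effect`):
#'   ordered-logit slope of the module factor on the symptom liability
#'   among current-status subjects.
#' @param status_effects Data frame (`module`, `remitted`, `current`):
#'   mean shift of the module's latent factor (in factor SD units) for
#'   the remitted and current diagnostic groups.
#' @param bmi_coupling BMI increase (kg/m^2) per SD of the second
#'   module's factor, coupling the immuno-metabolic block to adiposity.
#' @param prevalence Named proportions for (control, remitted, current).
#' @param seed Master seed; all sub-streams derive from it.
#' @return A validated `sim_config` object (list).
#' @export
sim_config <- function(n_subjects = 1621L,
                       n_analytes = 171L,
                       module_spec = default_module_spec(),
                       noise_sd = 1,
                       missing_rate_range = c(0, 0.10),
                       lod_censor_rate = 0.02,
                       planted_effects = default_planted_effects(),
                       status_effects = data.frame(module = 2L,
                                                   remitted = 0.05,
                                                   current = 0.16),
                       bmi_coupling = 2.0,
                       prevalence = c(control = 426, remitted = 483,
                                      current = 712) / 1621,
                       seed = 1L) {
  check_count(n_subjects, "n_subjects", min = 1L)
  check_count(n_analytes, "n_analytes", min = 1L)
  if (!is.data.frame(module_spec) ||
      !all(c("size", "loading_mean", "frac_negative") %in% names(module_spec))) {
    stop_bad("module_spec", "needs columns size, loading_mean, frac_negative")
  }
  if (nrow(module_spec) > 0) {
    if (any(module_spec$size < 1)) stop_bad("module_spec", "sizes must be >= 1")
    if (any(module_spec$loading_mean <= 0 | module_spec$loading_mean > 1)) {
      stop_bad("module_spec", "loading_mean must lie in (0, 1]")
    }
    check_proportion(module_spec$frac_negative, "module_spec$frac_negative",
                     allow_vec = TRUE)
    if (sum(module_spec$size) > n_analytes) {
      stop_bad("module_spec", "module sizes exceed n_analytes")
    }
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop_bad("noise_sd", "must be a non-negative number")
  }
  if (length(missing_rate_range) != 2L) {
    stop_bad("missing_rate_range", "must have length 2")
  }
  check_proportion(missing_rate_range, "missing_rate_range", allow_vec = TRUE)
  if (missing_rate_range[1] > missing_rate_range[2]) {
    stop_bad("missing_rate_range", "lower bound exceeds upper bound")
  }
  check_proportion(lod_censor_rate, "lod_censor_rate")
  if (!is.data.frame(planted_effects) ||
      !all(c("module", "symptom", "effect") %in% names(planted_effects))) {
    stop_bad("planted_effects", "needs columns module, symptom, effect")
  }
  # default effect tables are trimmed to the modules that exist; explicitly
  # supplied tables must reference real modules
  if (missing(planted_effects)) {
    planted_effects <-
      planted_effects[planted_effects$module <= nrow(module_spec), ,
                      drop = FALSE]
  }
  if (missing(status_effects) && is.data.frame(status_effects)) {
    status_effects <-
      status_effects[status_effects$module <= nrow(module_spec), ,
                     drop = FALSE]
  }
  if (nrow(planted_effects) > 0) {
    if (!all(is.finite(planted_effects$effect))) {
      stop_bad("planted_effects", "effect sizes must be finite")
    }
    if (any(planted_effects$module < 1 |
            planted_effects$module > max(1L, nrow(module_spec)))) {
      stop_bad("planted_effects", "module index out of range")
    }
    if (any(planted_effects$symptom < 1 | planted_effects$symptom > 30)) {
      stop_bad("planted_effects", "symptom index must be in 1..30")
    }
  }
  check_proportion(prevalence, "prevalence", allow_vec = TRUE)
  if (length(prevalence) != 3L || abs(sum(prevalence) - 1) > 1e-8) {
    stop_bad("prevalence", "must be 3 proportions summing to 1")
  }
  check_count(seed, "seed")

  structure(list(
    n_subjects = as.integer(n_subjects),
    n_analytes = as.integer(n_analytes),
    module_spec = module_spec,
    noise_sd = noise_sd,
    missing_rate_range = missing_rate_range,
    lod_censor_rate = lod_censor_rate,
    planted_effects = planted_effects,
    status_effects = status_effects,
    bmi_coupling = bmi_coupling,
    prevalence = stats::setNames(as.numeric(prevalence),
                                 c("control", "remitted", "current")),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Preprocessing configuration
#'
#' @param missing_threshold Analytes with a missing fraction strictly
#'   greater than this are excluded (default 0.30).
#' @param tie_method Rank tie handling for the inverse-normal transform;
#'   only average ranks are supported.
#' @param blom_offset Offset c in the rank-based inverse-normal
#'   transform \eqn{\Phi^{-1}((r - c)/(n - 2c + 1))}; 3/8 is the Blom
#'   convention.
#' @return A `preprocess_config` object.
#' @export
preprocess_config <- function(missing_threshold = 0.30,
                              tie_method = "average_rank",
                              blom_offset = 3 / 8) {
  if (!is.numeric(missing_threshold) || length(missing_threshold) != 1L ||
      missing_threshold <= 0 || missing_threshold >= 1) {
    stop_bad("missing_threshold", "must lie in (0, 1)")
  }
  tie_method <- match.arg(tie_method, "average_rank")
  if (!is.numeric(blom_offset) || blom_offset < 0 || blom_offset >= 0.5) {
    stop_bad("blom_offset", "must lie in [0, 0.5)")
  }
  structure(list(missing_threshold = missing_threshold,
                 tie_method = tie_method,
                 blom_offset = blom_offset),
            class = "preprocess_config")
}

#' Network construction configuration
#'
#' @param beta Soft-threshold power applied to the absolute correlation
#'   (default 4).
#' @param mode Network type; only the unsigned network (absolute
#'   correlation) is supported.
#' @param min_module_size Minimum number of analytes per module
#'   (default 5).
#' @param dissimilarity Clustering dissimilarity: `"tom"` (1 -
#'   topological overlap, default) or `"adjacency"` (1 - adjacency).
#' @param linkage Hierarchical clustering linkage; only average linkage
#'   is supported.
#' @param cut_method Branch pruning method; only the adaptive
#'   dendrogram-shape cut (`"dynamic_tree"`) is supported.
#' @param deep_split Split sensitivity, integer 0 (coarse) to 4 (fine);
#'   default 2.
#' @return A `network_config` object.
#' @export
network_config <- function(beta = 4,
                           mode = "unsigned",
                           min_module_size = 5L,
                           dissimilarity = c("tom", "adjacency"),
                           linkage = "average",
                           cut_method = "dynamic_tree",
                           deep_split = 2L) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 1) {
    stop_bad("beta", "must be >= 1")
  }
  mode <- match.arg(mode, "unsigned")
  check_count(min_module_size, "min_module_size", min = 2L)
  dissimilarity <- match.arg(dissimilarity)
  linkage <- match.arg(linkage, "average")
  cut_method <- match.arg(cut_method, "dynamic_tree")
  check_count(deep_split, "deep_split")
  if (deep_split > 4L) stop_bad("deep_split", "must be in 0..4")
  structure(list(beta = beta, mode = mode,
                 min_module_size = as.integer(min_module_size),
                 dissimilarity = dissimilarity, linkage = linkage,
                 cut_method = cut_method,
                 deep_split = as.integer(deep_split)),
            class = "network_config")
}

#' Split-half stability configuration
#'
#' @param iterations Number of split-half iterations (default 1000;
#'   each iteration contributes two half-sample clusterings).
#' @param seed Seed for the resampling stream.
#' @param reference_module Character vector of analyte identifiers
#'   defining the reference module (from the full-sample run).
#' @param network A [network_config()] used for every half-sample
#'   clustering (identical to the main run).
#' @return A `stability_config` object.
#' @export
stability_config <- function(iterations = 1000L,
                             seed = 1L,
                             reference_module,
                             network = network_config()) {
  check_count(iterations, "iterations", min = 1L)
  check_count(seed, "seed")
  if (missing(reference_module) || length(reference_module) == 0L) {
    stop_bad("reference_module", "must name at least one analyte")
  }
  if (!inherits(network, "network_config")) {
    stop_bad("network", "must be a network_config object")
  }
  structure(list(iterations = as.integer(iterations),
                 seed = as.integer(seed),
                 reference_module = as.character(reference_module),
                 network = network),
            class = "stability_config")
}
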