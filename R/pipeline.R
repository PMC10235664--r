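# End-to-end orchestration: simulate (or load) -> preprocess -> network ->
# association scans -> stability, with a JSON + markdown report.

#' Validate cohort input tables
#'
#' Checks subject-identifier alignment between the protein and
#' phenotype tables, analyte uniqueness, item score ranges, covariate
#' completeness and status levels. Fatal problems and warnings are
#' reported separately.
#'
#' @param proteins A `protein_matrix`.
#' @param phenotypes Phenotype data frame.
#' @param lod Optional detection-limit data frame.
#' @return List with character vectors `errors` and `warnings`.
#' @export
validate_inputs <- function(proteins, phenotypes, lod = NULL) {
  errors <- character(0)
  warnings <- character(0)
  subj_p <- subject_ids(proteins)
  subj_f <- as.character(phenotypes$subject_id)
  missing_pheno <- setdiff(subj_p, subj_f)
  if (length(missing_pheno)) {
    errors <- c(errors, sprintf(
      "subjects missing from phenotypes: %s",
      paste(utils::head(missing_pheno, 5), collapse = ", ")))
  }
  extra_pheno <- setdiff(subj_f, subj_p)
  if (length(extra_pheno)) {
    errors <- c(errors, sprintf(
      "subjects missing from proteins: %s",
      paste(utils::head(extra_pheno, 5), collapse = ", ")))
  }
  if (anyDuplicated(analyte_ids(proteins))) {
    errors <- c(errors, "duplicated analyte identifiers")
  }
  if (!all(levels(factor(phenotypes$status)) %in%
           c("control", "remitted", "current"))) {
    errors <- c(errors, "status must be control/remitted/current")
  }
  items <- grep("^ids_", names(phenotypes), value = TRUE)
  for (col in items) {
    bad <- !is.na(phenotypes[[col]]) & !phenotypes[[col]] %in% 0:3
    if (any(bad)) {
      errors <- c(errors, sprintf("item %s has scores outside 0..3", col))
    }
  }
  covs <- intersect(tier_covariates("bmi"), names(phenotypes))
  for (v in covs) {
    nmiss <- sum(is.na(phenotypes[[v]]))
    if (nmiss > 0) {
      warnings <- c(warnings, sprintf("covariate %s: %d missing values",
                                      v, nmiss))
    }
  }
  known <- c("subject_id", "status", "total_ids", items, tier_covariates("bmi"))
  extra <- setdiff(names(phenotypes), known)
  if (length(extra)) {
    warnings <- c(warnings, sprintf("unexpected phenotype columns: %s",
                                    paste(extra, collapse = ", ")))
  }
  if (!is.null(lod)) {
    unknown <- setdiff(lod$analyte, analyte_ids(proteins))
    if (length(unknown)) {
      warnings <- c(warnings, sprintf(
        "detection limits for unknown analytes: %s",
        paste(utils::head(unknown, 5), collapse = ", ")))
    }
  }
  list(errors = errors, warnings = warnings)
}

#' Run configuration for the full pipeline
#'
#' @param sim A [sim_config()] used when no input directory is given.
#' @param input_dir Optional directory with `proteins.tsv`,
#'   `phenotypes.tsv` and optionally `lod.tsv`; when supplied the
#'   simulation stage is skipped.
#' @param out_dir Output directory for tables and the report.
#' @param preprocess A [preprocess_config()].
#' @param network A [network_config()].
#' @param tier Adjustment tier for the association scans.
#' @param symptom_items Item indices for the symptom scans.
#' @param stability_iterations Split-half iterations (default 1000).
#' @param seed Global seed; per-stage seeds derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       input_dir = NULL,
                       out_dir = tempfile("protnet_run_"),
                       preprocess = preprocess_config(),
                       network = network_config(),
                       tier = "base",
                       symptom_items = 1:28,
                       stability_iterations = 1000L,
                       seed = 1L) {
  check_count(stability_iterations, "stability_iterations", min = 1L)
  check_count(seed, "seed")
  structure(list(sim = sim, input_dir = input_dir, out_dir = out_dir,
                 preprocess = preprocess, network = network, tier = tier,
                 symptom_items = symptom_items,
                 stability_iterations = as.integer(stability_iterations),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, preprocesses the panel, builds the
#' unsigned network and detects modules, computes eigenproteins and
#' kME, scans modules against current diagnosis, scans symptom items
#' for the selected module (high- and low-endorsement contrasts), runs
#' the split-half stability analysis on the selected module, and writes
#' a JSON + markdown report plus TSV tables under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return The report, invisibly (a list; element `paths` holds output
#'   file locations).
#' @export
run_all <- function(config = run_config()) {
  if (!inherits(config, "run_config")) {
    stop("`config` must be a run_config", call. = FALSE)
  }
  seeds <- seed_streams(config$seed, c("simulate", "stability"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- inputs
  if (is.null(config$input_dir)) {
    sim <- config$sim
    sim$seed <- as.integer(seeds["simulate"] %% .Machine$integer.max)
    cohort <- simulate_cohort(sim)
    cohort$proteins <- inject_missingness(cohort$proteins, sim)
    proteins <- cohort$proteins
    phenotypes <- cohort$phenotypes
  } else {
    proteins <- read_protein_matrix(
      file.path(config$input_dir, "proteins.tsv"),
      lod_path = {
        p <- file.path(config$input_dir, "lod.tsv")
        if (file.exists(p)) p else NULL
      })
    phenotypes <- read_phenotypes(file.path(config$input_dir, "phenotypes.tsv"))
  }
  chk <- validate_inputs(proteins, phenotypes, proteins$lod)
  if (length(chk$errors)) {
    stop(sprintf("input validation failed: %s",
                 paste(chk$errors, collapse = "; ")), call. = FALSE)
  }

  # --- preprocess
  prep <- preprocess(proteins, config$preprocess)
  transformed <- prep$proteins
  imputed_for_stability <- impute_matrix(
    filter_by_missingness(proteins, config$preprocess)$proteins)

  # --- network
  R <- correlation_matrix(transformed)
  A <- soft_threshold_adjacency(R, config$network)
  sft <- tryCatch(scale_free_fit(A), error = function(e) {
    list(r_squared = NA_real_, slope = NA_real_)
  })
  D <- if (config$network$dissimilarity == "tom") {
    1 - topological_overlap(A)
  } else 1 - A
  diag(D) <- 0
  partition <- detect_modules(D, config$network)
  K <- length(partition$module_sizes)
  if (K < 1) stop("no modules detected", call. = FALSE)
  eps <- eigenprotein_set(transformed, partition)
  asg <- partition$assignment
  module_table <- data.frame(
    module = paste0("EP", seq_len(K)),
    size = partition$module_sizes,
    variance_explained = unname(eps$variance_explained),
    mean_abs_within_cor = vapply(seq_len(K), function(m) {
      mean_abs_within_correlation(R, names(asg)[asg == m])
    }, numeric(1))
  )

  # --- association scans
  status_scan <- scan_clusters_vs_status(eps, phenotypes, config$tier)
  sel <- which(status_scan$selected)[1]
  sel_scores <- eps$scores[, sel, drop = FALSE]
  symptoms_high <- scan_symptoms(sel_scores, phenotypes, config$tier,
                                 "current_high_vs_control",
                                 config$symptom_items)
  symptoms_low <- scan_symptoms(sel_scores, phenotypes, config$tier,
                                "current_low_vs_control",
                                config$symptom_items)

  # Bonferroni multipliers must equal the counts actually tested
  stopifnot(all(status_scan$multiplier == nrow(status_scan)),
            all(symptoms_high$multiplier == nrow(symptoms_high)))

  # --- stability of the selected module
  ref <- names(asg)[asg == sel]
  stab_cfg <- stability_config(
    iterations = config$stability_iterations,
    seed = as.integer(seeds["stability"] %% .Machine$integer.max),
    reference_module = ref,
    network = config$network)
  stability <- run_stability(imputed_for_stability, stab_cfg)

  report <- list(
    seed = config$seed,
    stage_seeds = as.list(seeds),
    n_subjects = nrow(transformed$values),
    n_analytes_input = ncol(proteins$values),
    n_analytes_used = ncol(transformed$values),
    excluded_analytes = prep$excluded$analyte,
    scale_free = list(r_squared = sft$r_squared, slope = sft$slope),
    modules = module_table,
    n_unassigned = sum(asg == 0),
    status_scan = status_scan,
    selected_module = status_scan$module[sel],
    symptoms_high = symptoms_high,
    symptoms_low = symptoms_low,
    stability = c(stability$summary,
                  list(reference_size = length(ref)))
  )

  # --- outputs
  paths <- write_report(report, partition, eps, stability, config$out_dir)
  report$paths <- paths
  invisible(report)
}

write_report <- function(report, partition, eps, stability, out_dir) {
  paths <- list()
  tw <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths$partition <- tw(data.frame(analyte = names(partition$assignment),
                                   module = unname(partition$assignment)),
                        "partition.tsv")
  paths$eigenproteins <- tw(data.frame(subject_id = rownames(eps$scores),
                                       eps$scores, check.names = FALSE),
                            "eigenproteins.tsv")
  paths$kme <- tw(eps$kme, "kme.tsv")
  paths$status <- tw(report$status_scan, "status_scan.tsv")
  paths$symptoms_high <- tw(report$symptoms_high, "symptoms_high.tsv")
  paths$symptoms_low <- tw(report$symptoms_low, "symptoms_low.tsv")
  paths$frequencies <- tw(data.frame(analyte = names(stability$frequency),
                                     frequency = unname(stability$frequency),
                                     percent = 100 * unname(stability$frequency)),
                          "stability_frequencies.tsv")
  paths$report_json <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, paths$report_json, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  paths$report_md <- file.path(out_dir, "report.md")
  writeLines(render_report_md(report), paths$report_md)
  paths
}

render_report_md <- function(report) {
  md <- c(
    "# Proteomic network analysis report", "",
    sprintf("- subjects: %d", report$n_subjects),
    sprintf("- analytes: %d used of %d (excluded: %d)",
            report$n_analytes_used, report$n_analytes_input,
            length(report$excluded_analytes)),
    sprintf("- scale-free fit: R^2 = %.3f, slope = %.2f",
            report$scale_free$r_squared, report$scale_free$slope),
    "", "## Modules", "",
    "| module | size | variance explained | mean |r| within |",
    "|---|---|---|---|",
    sprintf("| %s | %d | %.3f | %.3f |",
            report$modules$module, report$modules$size,
            report$modules$variance_explained,
            report$modules$mean_abs_within_cor),
    sprintf("| unassigned | %d | | |", report$n_unassigned),
    "", "## Diagnosis scan (current vs control)", "",
    "| module | estimate | p | adj. p | |",
    "|---|---|---|---|---|",
    sprintf("| %s | %.3f | %.3g | %.3g | %s |",
            report$status_scan$module, report$status_scan$estimate,
            report$status_scan$p, report$status_scan$p_bonferroni,
            ifelse(report$status_scan$selected, "selected", "")),
    "", sprintf("## Symptom scan, high endorsement (module %s)",
                report$selected_module), "",
    "| item | estimate | p | adj. p |",
    "|---|---|---|---|",
    sprintf("| %s | %.3f | %.3g | %.3g |",
            report$symptoms_high$item, report$symptoms_high$estimate,
            report$symptoms_high$p, report$symptoms_high$p_bonferroni),
    "", "## Stability (split-half)", "",
    sprintf("- best-overlap module size: %.1f (sd %.1f)",
            report$stability$mean_size, report$stability$sd_size),
    sprintf("- overlap with reference: %.1f (sd %.1f) of %d",
            report$stability$mean_overlap, report$stability$sd_overlap,
            report$stability$reference_size)
  )
  md
}
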