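# End-to-end pipeline: size-distribution analysis -> reproductive
# accounting -> yolk budgets -> composition statistics, with a manifest
# that makes reruns byte-comparable.

#' Pipeline configuration
#'
#' @param input_dir directory holding `follicles.csv`, `ovaries.csv` and
#'   optionally `composition.csv`; leave `NULL` to simulate instead.
#' @param simulate a [cohort_spec()] used when `input_dir` is `NULL`.
#' @param threshold `"derive"` (default) to derive the dominance threshold
#'   from a two-cluster fit, or a numeric override in mm within (4, 37).
#' @param constants an [energetic_constants()].
#' @param dry_weight `"printed"` for the default regression or `"refit"`
#'   to re-estimate it from measured (diameter, dry mass) pairs.
#' @param alpha significance level for composition follow-ups.
#' @param n_monte_carlo dip-test Monte-Carlo draws.
#' @param gating composition decision rule (see [composition_report()]).
#' @param rng_seed integer seed for every stochastic step.
#' @param output_dir where reports are written.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL,
                            simulate = cohort_spec(),
                            threshold = "derive",
                            constants = energetic_constants(),
                            dry_weight = c("printed", "refit"),
                            alpha = 0.05,
                            n_monte_carlo = 999L,
                            gating = "default",
                            rng_seed = 1L,
                            output_dir = tempfile("vitellus_run_")) {
  dry_weight <- match.arg(dry_weight)
  if (is.numeric(threshold)) {
    if (threshold <= 4 || threshold >= 37) {
      stop("numeric threshold override must lie in (4, 37) mm")
    }
  } else if (!identical(threshold, "derive")) {
    stop("threshold must be \"derive\" or a number in (4, 37)")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(input_dir = input_dir, simulate = simulate,
                 threshold = threshold, constants = constants,
                 dry_weight = dry_weight, alpha = alpha,
                 n_monte_carlo = as.integer(n_monte_carlo),
                 gating = gating, rng_seed = as.integer(rng_seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: (1) clustering — dip test of the pooled diameter
#' distribution, cluster-count selection, two-cluster fit and threshold
#' derivation (or the configured override); (2) accounting — per-female
#' clutch summary and ovary-symmetry report; (3) budget — per-female yolk
#' budgets and the cohort summary; (4) composition statistics.  Writes
#' `clustering_report.csv`, `reproductive_summary.csv`,
#' `symmetry_report.csv`, `energy_budget.csv`, `budget_summary.csv`,
#' `composition_report.csv` and `manifest.txt` into the output directory.
#' Identical config and seed reproduce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all stage results and `paths`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  stage <- "load"
  result <- tryCatch(
    run_pipeline_impl(config),
    vitellus_stage_error = function(e) {
      stop(sprintf("pipeline aborted at stage '%s': %s",
                   e$stage, conditionMessage(e)), call. = FALSE)
    })
  result
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    cond <- structure(class = c("vitellus_stage_error", "error", "condition"),
                      list(message = conditionMessage(e), call = NULL,
                           stage = stage))
    stop(cond)
  })
}

run_pipeline_impl <- function(config) {
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- load or simulate -----------------------------------------------
  inputs <- stage_try("load", {
    if (is.null(config$input_dir)) {
      spec <- config$simulate
      spec$rng_seed <- config$rng_seed
      cohort <- generate_cohort(do.call(cohort_spec, unclass(spec)))
      list(follicles = cohort$follicles, ovaries = cohort$ovaries,
           composition = cohort$composition, truth = cohort$truth)
    } else {
      comp_path <- file.path(config$input_dir, "composition.csv")
      list(follicles = read_follicles(file.path(config$input_dir,
                                                "follicles.csv")),
           ovaries = read_ovaries(file.path(config$input_dir, "ovaries.csv")),
           composition = if (file.exists(comp_path))
             read_composition(comp_path) else NULL,
           truth = NULL)
    }
  })

  # --- clustering ------------------------------------------------------
  clustering <- stage_try("clustering", {
    diam <- inputs$follicles$diameter_mm
    if (length(diam) < 4) stop("too few follicles to analyse")
    dip <- dip_test(diam, n_monte_carlo = config$n_monte_carlo,
                    rng_seed = config$rng_seed)
    ks <- select_k(diam, candidate_ks = 1:6)
    model <- kmeans_1d(diam, 2L)
    derived <- derive_dominance_threshold(model)
    threshold <- if (identical(config$threshold, "derive")) derived
                 else config$threshold
    list(dip = dip, k_selection = ks, model = model,
         derived_threshold = derived, threshold = threshold)
  })

  # --- accounting ------------------------------------------------------
  accounting <- stage_try("accounting", {
    records <- as_female_records(inputs$follicles, inputs$ovaries)
    summary <- reproductive_summary(records, clustering$threshold,
                                    config$constants$mean_clutch_size)
    symmetry <- tryCatch(
      suppressMessages(ovary_symmetry_report(records, clustering$threshold)),
      error = function(e) NULL)
    growth <- vapply(records, function(fem) {
      tryCatch(follicle_growth_pct(fem, clustering$threshold),
               error = function(e) NA_real_)
    }, numeric(1))
    list(records = records, summary = summary, symmetry = symmetry,
         mean_growth_pct = mean(growth, na.rm = TRUE))
  })

  # --- budget ----------------------------------------------------------
  budget <- stage_try("budget", {
    model <- if (config$dry_weight == "refit") {
      fit_dry_weight_model(inputs$follicles$diameter_mm,
                           inputs$follicles$dry_mass_g)
    } else {
      dry_weight_model()
    }
    budgets <- suppressMessages(
      cohort_budget(accounting$records, clustering$threshold,
                    composition = inputs$composition, model = model,
                    constants = config$constants))
    summary <- cohort_budget_summary(budgets, config$constants)
    seasonal <- tryCatch(seasonal_follicle_comparison(accounting$summary),
                         error = function(e) NULL)
    list(model = model, budgets = budgets, summary = summary,
         seasonal = seasonal)
  })

  # --- composition stats ----------------------------------------------
  composition <- stage_try("composition", {
    if (is.null(inputs$composition) || nrow(inputs$composition) == 0L) {
      NULL
    } else {
      suppressMessages(composition_report(inputs$composition,
                                          alpha = config$alpha,
                                          gating = config$gating))
    }
  })

  # --- reports ---------------------------------------------------------
  paths <- stage_try("report", {
    ks <- clustering$k_selection
    clust_df <- data.frame(
      metric = c("dip_D", "dip_p", "n_follicles", "elbow_k", "silhouette_k",
                 "centre_lower_mm", "centre_upper_mm", "min_upper_cluster_mm",
                 "derived_threshold_mm", "threshold_mm"),
      value = c(clustering$dip$statistic_D, clustering$dip$p_value,
                clustering$dip$n, ks$elbow_k, ks$silhouette_k,
                clustering$model$centres[1], clustering$model$centres[2],
                clustering$model$min_of_upper_cluster,
                clustering$derived_threshold, clustering$threshold))
    p <- c(clustering = file.path(out_dir, "clustering_report.csv"),
           reproductive = file.path(out_dir, "reproductive_summary.csv"),
           symmetry = file.path(out_dir, "symmetry_report.csv"),
           budget = file.path(out_dir, "energy_budget.csv"),
           budget_summary = file.path(out_dir, "budget_summary.csv"),
           composition = file.path(out_dir, "composition_report.csv"),
           manifest = file.path(out_dir, "manifest.txt"))
    write.csv(clust_df, p[["clustering"]], row.names = FALSE)
    write.csv(accounting$summary, p[["reproductive"]], row.names = FALSE)
    if (!is.null(accounting$symmetry)) {
      write.csv(accounting$symmetry, p[["symmetry"]], row.names = FALSE)
    }
    write.csv(budget$budgets, p[["budget"]], row.names = FALSE)
    write.csv(budget$summary$summary, p[["budget_summary"]], row.names = FALSE)
    if (!is.null(composition)) {
      write.csv(composition$table, p[["composition"]], row.names = FALSE)
    }
    manifest <- c(
      sprintf("package_version: %s",
              as.character(utils::packageVersion("vitellus"))),
      sprintf("rng_seed: %d", config$rng_seed),
      sprintf("threshold: %s", paste(config$threshold, collapse = " ")),
      sprintf("threshold_used_mm: %s", clustering$threshold),
      sprintf("dry_weight: %s", config$dry_weight),
      sprintf("alpha: %g", config$alpha),
      sprintf("n_monte_carlo: %d", config$n_monte_carlo),
      sprintf("n_follicle_rows: %d", nrow(inputs$follicles)),
      sprintf("n_ovary_rows: %d", nrow(inputs$ovaries)),
      sprintf("n_composition_rows: %d",
              if (is.null(inputs$composition)) 0L
              else nrow(inputs$composition)),
      sprintf("n_females: %d", nrow(accounting$summary)),
      sprintf("deficit_fraction: %.10g", budget$summary$deficit_fraction))
    writeLines(manifest, p[["manifest"]])
    p
  })

  invisible(list(inputs = inputs, clustering = clustering,
                 accounting = accounting, budget = budget,
                 composition = composition, paths = paths,
                 config = config))
}
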