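#' Configuration for the full analysis pipeline
#'
#' One flat configuration object holding everything [run_pipeline()] needs.
#' Exactly one of `cohort_path` (read an existing cohort CSV) or
#' `params` + `design` (synthesize one) must be given.  Every
#' study-protocol constant (4 chains, 15,000 iterations, 5,000 burn-in,
#' false-positive prior upper bound 0.01, balanced prevalence 0.5) lives
#' in the nested `priors`, `control` and threshold settings, defaulted to
#' the protocol values.
#'
#' @param cohort_path Path to a cohort CSV, or `NULL` to synthesize.
#' @param params [lca_params()] generating truth for synthesis.
#' @param design [cohort_design()] for synthesis.
#' @param priors [eiph_priors()] object.
#' @param control [eiph_mcmc_control()] object.
#' @param prevalence Assumed prevalence for precision/F1.
#' @param mean_type F1 variant, `"harmonic"` or `"geometric"`.
#' @param strict_threshold Use the strict `>` BALFRBC positivity rule in
#'   the cross-tabulation (default `FALSE`, the `>=` rule).
#' @param run_sensitivity Run the +/-10% false-positive prior sensitivity
#'   analysis (two extra full fits).
#' @param sensitivity_scales Multipliers for the sensitivity analysis.
#' @param outdir Output directory for artifact files, or `NULL` for none.
#' @return An object of class `"eiph_pipeline_config"`.
#' @export
pipeline_config <- function(cohort_path = NULL, params = NULL,
                            design = NULL, priors = eiph_priors(),
                            control = eiph_mcmc_control(),
                            prevalence = 0.5,
                            mean_type = c("harmonic", "geometric"),
                            strict_threshold = FALSE,
                            run_sensitivity = FALSE,
                            sensitivity_scales = c(0.9, 1.0, 1.1),
                            outdir = NULL) {
  mean_type <- match.arg(mean_type)
  synth <- !is.null(params) || !is.null(design)
  if (is.null(cohort_path) && !synth)
    stop("give either cohort_path or synthesis params/design", call. = FALSE)
  if (!is.null(cohort_path) && synth)
    stop("give cohort_path or synthesis params/design, not both",
         call. = FALSE)
  if (synth) {
    if (is.null(params)) params <- default_study_params()
    if (is.null(design)) design <- cohort_design()
  }
  structure(list(cohort_path = cohort_path, params = params,
                 design = design, priors = priors, control = control,
                 prevalence = prevalence, mean_type = mean_type,
                 strict_threshold = strict_threshold,
                 run_sensitivity = run_sensitivity,
                 sensitivity_scales = sensitivity_scales,
                 outdir = outdir),
            class = "eiph_pipeline_config")
}

#' Run the full EIPH diagnostic-accuracy pipeline
#'
#' Sequences the analysis stages: obtain the cohort (read or synthesize),
#' compute the descriptive layer (per-score summary table, all-score
#' overlap interval, tied-rank correlation, repeat-lavage repeated-measures
#' comparison, pooled sedentary summary), fit the latent-class model, take
#' the MAP estimate, build the model-based ROC curve, locate the
#' F1-optimal BALFRBC threshold, cross-tabulate both tests at that
#' threshold, and optionally run the false-positive prior sensitivity
#' analysis.  Reruns with an identical configuration produce identical
#' reports.
#'
#' @param config An [eiph_pipeline_config()] object.
#' @return A list of class `"eiph_report"` with elements `config_echo`,
#'   `cohort_size`, `descriptives`, `posterior`, `tbe_accuracy`,
#'   `balf_accuracy`, `map`, `threshold`, `crosstab`, `convergence`, and
#'   (optionally) `prior_sensitivity`.  If `config$outdir` is set, also
#'   writes `cohort.csv`, `posterior_summary.csv`, `draws.csv`, `roc.csv`,
#'   `score_summary.csv` and `report.json` there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "eiph_pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("cohort", {
    if (!is.null(config$cohort_path)) read_cohort(config$cohort_path)
    else simulate_cohort(config$params, config$design)
  })

  desc <- stage("descriptives", {
    ex <- cohort[cohort$group == "exercised", , drop = FALSE]
    sed <- cohort[cohort$group == "sedentary", , drop = FALSE]
    tab <- score_summary_table(ex)
    out <- list(score_summary = tab,
                overlap = if (nrow(tab) >= 2) overlap_interval(tab) else NULL,
                spearman = if (length(unique(ex$tbe_score)) >= 2)
                  spearman_tied(ex$tbe_score, ex$balf_rbc) else NULL)
    if (nrow(sed) > 0 && length(unique(sed$occasion)) >= 2) {
      out$repeat_lavage <- repeated_measures_anova(
        sed$balf_rbc, sed$occasion, sed$horse_id)
      gm <- tapply(sed$balf_rbc, sed$occasion, mean)
      gs <- tapply(sed$balf_rbc, sed$occasion, stats::sd)
      gn <- tapply(sed$balf_rbc, sed$occasion, length)
      out$sedentary_pooled <- pooled_summary(gn, gm, gs)
    }
    out
  })

  fit <- stage("fit", eiph_lca(cohort, config$priors, config$control))
  map <- stage("map", map_estimate(fit))
  roc <- stage("roc", roc_from_normals(map, prevalence = config$prevalence,
                                       mean_type = config$mean_type))
  thr <- stage("threshold",
               optimal_threshold(map, prevalence = config$prevalence,
                                 mean_type = config$mean_type))
  xt <- stage("crosstab", cross_tabulate(
    cohort[cohort$group == "exercised", , drop = FALSE],
    threshold = thr$threshold_natural, strict = config$strict_threshold))
  sens <- NULL
  if (isTRUE(config$run_sensitivity))
    sens <- stage("prior_sensitivity",
                  prior_sensitivity(cohort, config$priors, config$control,
                                    config$sensitivity_scales))

  s <- summary(fit)
  report <- list(
    config_echo = list(
      seed = config$control$seed,
      synthesized = is.null(config$cohort_path),
      cohort_seed = if (!is.null(config$design)) config$design$seed else NULL,
      n_chains = config$control$n_chains,
      n_iterations = config$control$n_iterations,
      n_burn_in = config$control$n_burn_in,
      fpr_prior_upper = config$priors$fpr_prior_range[2],
      prevalence_assumed = config$prevalence,
      mean_type = config$mean_type,
      strict_threshold = config$strict_threshold),
    cohort_size = list(
      n_exercised = sum(cohort$group == "exercised"),
      n_sedentary = sum(cohort$group == "sedentary")),
    descriptives = desc,
    posterior = fit$summary,
    tbe_accuracy = s$tbe_accuracy,
    balf_accuracy = balf_metrics(fit, thr$threshold_natural),
    map = unclass(map),
    threshold = unclass(thr),
    crosstab = unclass(xt),
    convergence = list(converged = fit$converged,
                       max_rhat = max(fit$summary$rhat, na.rm = TRUE)))
  if (!is.null(sens))
    report$prior_sensitivity <- list(
      means = sens$means, max_abs_deviation = sens$max_abs_deviation)
  class(report) <- "eiph_report"

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$outdir, f)
    write_cohort(cohort, p("cohort.csv"))
    utils::write.csv(fit$summary, p("posterior_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(fit$draws, p("draws.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(roc), p("roc.csv"), row.names = FALSE)
    utils::write.csv(desc$score_summary, p("score_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(strip_classes(report), p("report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", force = TRUE)
  }
  report
}

# jsonlite serializes plain lists/data frames predictably
strip_classes <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}

#' @export
print.eiph_report <- function(x, ...) {
  cat("EIPH diagnostic-accuracy pipeline report\n")
  cat(sprintf("  cohort: %d exercised, %d sedentary\n",
              x$cohort_size$n_exercised, x$cohort_size$n_sedentary))
  if (!is.null(x$descriptives$spearman))
    cat(sprintf("  Spearman rho (TBE score vs BALFRBC): %.2f (p = %.3g)\n",
                x$descriptives$spearman$rho,
                x$descriptives$spearman$p_value))
  cat(sprintf("  F1-optimal threshold: %.0f cells/uL\n",
              round(x$threshold$threshold_natural)))
  cat(sprintf("  TBE sensitivity %.2f, specificity %.3f\n",
              x$tbe_accuracy$mean[1], x$tbe_accuracy$mean[2]))
  cat(sprintf("  BALFRBC sensitivity %.2f, specificity %.2f at threshold\n",
              x$balf_accuracy$mean[1], x$balf_accuracy$mean[2]))
  cat(sprintf("  converged: %s (max split R-hat %.3f)\n",
              x$convergence$converged, x$convergence$max_rhat))
  invisible(x)
}
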