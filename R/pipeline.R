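# End-to-end orchestration: simulate or ingest, derive, assign ethnicity,
# summarize, associate, fit cutoffs, screen, and write the report bundle.

#' Analysis configuration
#'
#' Parameters of the end-to-end analysis: grouping variable, metrics, the
#' significant-tumor-volume threshold, the published screening cutoffs used
#' for the fixed-cutoff classification (PSAD 0.15, PSAMD 0.012), the fixed
#' specificity of the sensitivity comparison (0.80), bootstrap resamples,
#' and the root seed.
#'
#' @param grouping stratification column (default "race_ethnicity").
#' @param metrics the PSA-based tests to analyse.
#' @param tv_threshold cm^3 (default 0.5, must be > 0).
#' @param published_cutoffs named vector of fixed screening cutoffs.
#' @param fixed_specificity specificity for the sensitivity comparison,
#'   in (0, 1).
#' @param n_boot bootstrap resamples for the metric comparison.
#' @param seed root integer seed for every stochastic stage.
#' @param bsa_mode "meters" or "dubois-cm", see \code{\link{compute_bsa}}.
#' @return validated list of class \code{analysis_config}.
#' @export
analysis_config <- function(grouping = "race_ethnicity",
                            metrics = c("psa", "psad", "psam", "psamd"),
                            tv_threshold = 0.5,
                            published_cutoffs = c(psad = 0.15,
                                                  psamd = 0.012),
                            fixed_specificity = 0.80,
                            n_boot = 2000,
                            seed = NA_integer_,
                            bsa_mode = "meters") {
  if (tv_threshold <= 0) stop("tv_threshold must be > 0")
  if (fixed_specificity <= 0 || fixed_specificity >= 1)
    stop("fixed_specificity must be in (0, 1)")
  if (n_boot < 1) stop("n_boot must be >= 1")
  structure(list(grouping = grouping, metrics = metrics,
                 tv_threshold = tv_threshold,
                 published_cutoffs = published_cutoffs,
                 fixed_specificity = fixed_specificity,
                 n_boot = n_boot, seed = seed, bsa_mode = bsa_mode),
            class = "analysis_config")
}

# Stage seeds derive deterministically from the root seed so that each
# stochastic stage is independently reproducible; offsets are arbitrary
# fixed small integers, kept below .Machine$integer.max.
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, bootstrap = 2L)
  as.integer((as.integer(seed) * 1000L + offsets[[stage]]) %% 2147483647L)
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one cohort: derivative computation,
#' surname-based ethnicity assignment (when surnames are present), group
#' summaries by race/ethnicity and institution, per-group per-metric
#' optimal-cutoff analysis, fixed-cutoff screening classification at the
#' published cutoffs, and the fixed-specificity bootstrap comparison of
#' PSAMD against PSAD.  With \code{output_dir} set, writes the report
#' bundle: \code{table_race.csv}, \code{table_institution.csv},
#' \code{cutoff_table.csv}, \code{roc_points_<metric>.csv},
#' \code{screening_<metric>.csv}, and \code{manifest.yaml} (config, seed,
#' package version — sufficient to reproduce every output).
#'
#' @param cohort a \code{psa_cohort}, or NULL to simulate one from
#'   \code{preset}.
#' @param config an \code{\link{analysis_config}}.
#' @param preset generator preset name used when \code{cohort} is NULL.
#' @param output_dir optional directory for the report bundle.
#' @return list of class \code{psa_pipeline}: \code{derived},
#'   \code{summary_race}, \code{summary_institution}, \code{fit}
#'   (the \code{\link{cutoff_analysis}}), \code{screening} (per published
#'   cutoff), \code{sens_comparison}, \code{config}.
#' @export
run_pipeline <- function(cohort = NULL,
                         config = analysis_config(seed = 1),
                         preset = "table1_default",
                         output_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.na(config$seed)) stop("analysis_config needs a seed")
  if (is.null(cohort)) {
    cohort <- generate_cohort(cohort_preset(preset),
                              seed = derive_seed(config$seed, "simulate"))
  }
  derived <- derive_all(cohort, bsa_mode = config$bsa_mode,
                        tv_threshold = config$tv_threshold)
  if (any(!is.na(derived$surname))) {
    derived <- suppressWarnings(assign_ethnicity(derived))
  }

  summary_race <- summarize_groups(derived, "race_ethnicity")
  summary_inst <- summarize_groups(derived, "institution")
  fit <- cutoff_analysis(derived, metrics = config$metrics,
                         group = config$grouping,
                         tv_threshold = config$tv_threshold)

  screening <- lapply(names(config$published_cutoffs), function(m) {
    screening_classification(derived, m, config$published_cutoffs[[m]],
                             group = config$grouping,
                             tv_threshold = config$tv_threshold)
  })
  names(screening) <- names(config$published_cutoffs)

  labels <- classify_significant(derived$tumor_volume, config$tv_threshold)
  ok <- !is.na(derived$psamd) & !is.na(derived$psad) & !is.na(labels)
  sens_cmp <- compare_sensitivity_bootstrap(
    derived$psamd[ok], derived$psad[ok], labels[ok],
    spec_target = config$fixed_specificity, n_boot = config$n_boot,
    seed = derive_seed(config$seed, "bootstrap"))

  result <- structure(list(derived = derived, summary_race = summary_race,
                           summary_institution = summary_inst, fit = fit,
                           screening = screening,
                           sens_comparison = sens_cmp, config = config),
                      class = "psa_pipeline")
  if (!is.null(output_dir)) write_bundle(result, output_dir)
  result
}

#' @export
print.psa_pipeline <- function(x, ...) {
  cat(sprintf("<psa_pipeline> %d records, seed %d\n", nrow(x$derived),
              x$config$seed))
  print(summary(x$fit))
  cat(sprintf(
    "\nSensitivity at %.0f%% specificity: PSAMD %.3f vs PSAD %.3f (diff %+.3f, bootstrap p = %.3f)\n",
    100 * x$config$fixed_specificity, x$sens_comparison$sens_a,
    x$sens_comparison$sens_b, x$sens_comparison$diff,
    x$sens_comparison$p_value))
  invisible(x)
}

#' Render a summary or cutoff table to CSV
#'
#' \code{style = "characteristics"} renders a \code{\link{summarize_groups}}
#' result with one Mean and one Median(Min, Max) column per group;
#' \code{style = "cutoffs"} renders a \code{\link{cutoff_analysis}} table at
#' the reporting precisions (cutoffs 2 dp, PSAMD 3 dp; rates and AUC as
#' percentages at 1 dp).
#'
#' @param report a \code{group_summary} or \code{cutoff_analysis}.
#' @param path output CSV path.
#' @param style "characteristics" or "cutoffs".
#' @return (invisibly) the rendered data.frame.
#' @export
render_table <- function(report, path,
                         style = c("characteristics", "cutoffs")) {
  style <- match.arg(style)
  out <- if (style == "characteristics") {
    stopifnot(inherits(report, "group_summary"))
    cont <- report$continuous
    if (nrow(cont) == 0) stop("empty report")
    wide <- NULL
    for (g in names(report$group_n)) {
      sub <- cont[cont$group == g, ]
      block <- data.frame(
        mean = round(sub$mean, 3),
        median_min_max = sprintf("%.3g(%.3g, %.3g)", sub$median, sub$min,
                                 sub$max))
      names(block) <- paste0(g, c("_mean", "_median_min_max"))
      wide <- if (is.null(wide))
        cbind(data.frame(variable = sub$variable), block)
      else cbind(wide, block)
    }
    wide
  } else {
    stopifnot(inherits(report, "cutoff_analysis"))
    if (nrow(report$table) == 0) stop("empty report")
    format_cutoff_table(report$table)
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(out)
}

write_bundle <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  render_table(result$summary_race, file.path(output_dir, "table_race.csv"),
               "characteristics")
  render_table(result$summary_institution,
               file.path(output_dir, "table_institution.csv"),
               "characteristics")
  render_table(result$fit, file.path(output_dir, "cutoff_table.csv"),
               "cutoffs")
  for (m in result$config$metrics) {
    pts <- do.call(rbind, lapply(names(result$fit$rocs), function(g) {
      roc <- result$fit$rocs[[g]][[m]]
      if (is.null(roc)) return(NULL)
      cbind(group = g, roc$points)
    }))
    if (!is.null(pts)) {
      utils::write.csv(pts,
                       file.path(output_dir,
                                 paste0("roc_points_", m, ".csv")),
                       row.names = FALSE)
    }
  }
  for (m in names(result$screening)) {
    scr <- result$screening[[m]]
    per_record <- data.frame(id = result$derived$id,
                             group = result$derived[[result$config$grouping]],
                             score = result$derived[[m]],
                             tumor_volume = result$derived$tumor_volume,
                             label = scr$labels)
    utils::write.csv(per_record,
                     file.path(output_dir, paste0("screening_", m, ".csv")),
                     row.names = FALSE)
  }
  manifest <- list(
    package = "psadens",
    version = as.character(utils::packageVersion("psadens")),
    seed = result$config$seed,
    n_records = nrow(result$derived),
    config = unclass(result$config))
  manifest$config$published_cutoffs <- as.list(manifest$config$published_cutoffs)
  yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  invisible(output_dir)
}
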