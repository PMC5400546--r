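# The central estimator: race/ethnicity-stratified ROC analysis of the PSA
# derivatives against dichotomized tumor volume, with upper-left optimal
# cutoff selection.  Returned as a classed object in the classic modelling
# idiom (print / summary / coef / predict / plot).

#' Fit race/ethnicity-stratified optimal screening cutoffs
#'
#' For each group x metric combination, builds the ROC curve of the metric
#' against significant tumor volume (>= \code{tv_threshold} cm^3), selects
#' the optimal cutoff at the most upper-left point of the curve, and
#' records the resulting sensitivity, specificity, PPV, NPV and AUC — the
#' cutoff-table analysis of the workflow.  Groups in which only one outcome
#' class occurs are flagged not estimable rather than dropped.
#'
#' @param data a cohort passed through \code{\link{derive_all}} (must
#'   contain the metric columns and \code{tumor_volume}).
#' @param metrics score columns to analyse; default the four PSA-based
#'   tests.
#' @param group stratifying column (default "race_ethnicity"); NULL fits
#'   one unstratified stratum "All".
#' @param tv_threshold significant tumor volume in cm^3 (default 0.5).
#' @param criterion cutoff criterion, "upper_left" (default) or "youden";
#'   see \code{\link{optimal_cutoff}}.
#' @return object of class \code{cutoff_analysis}: list with
#'   \code{table} (one row per group x metric: group, metric, n, n_pos,
#'   cutoff, sensitivity, specificity, ppv, npv, auc, estimable),
#'   \code{rocs} (nested list of \code{psa_roc}), and the call arguments.
#' @examples
#' d <- derive_all(generate_cohort(cohort_preset("table1_default", seed = 1)))
#' fit <- cutoff_analysis(d)
#' coef(fit)          # cutoff matrix, groups x metrics
#' summary(fit)
#' @export
cutoff_analysis <- function(data,
                            metrics = c("psa", "psad", "psam", "psamd"),
                            group = "race_ethnicity", tv_threshold = 0.5,
                            criterion = c("upper_left", "youden")) {
  criterion <- match.arg(criterion)
  x <- as.data.frame(data)
  missing_m <- setdiff(metrics, names(x))
  if (length(missing_m) > 0)
    stop("metric column(s) not in data (run derive_all first?): ",
         paste(missing_m, collapse = ", "))
  if (!"tumor_volume" %in% names(x)) stop("data lacks tumor_volume")
  if (is.null(group)) {
    x$.group <- "All"
    group <- ".group"
  } else if (!group %in% names(x)) {
    stop("grouping column not in data: ", group)
  }
  labels_all <- classify_significant(x$tumor_volume, tv_threshold)

  strata <- split(seq_len(nrow(x)), x[[group]])
  rows <- list()
  rocs <- list()
  for (g in names(strata)) {
    idx <- strata[[g]]
    rocs[[g]] <- list()
    for (m in metrics) {
      scores <- x[[m]][idx]
      labels <- labels_all[idx]
      keep <- !is.na(scores) & !is.na(labels)
      estimable <- any(labels[keep]) && any(!labels[keep])
      if (estimable) {
        roc <- build_roc(scores[keep], labels[keep])
        opt <- optimal_cutoff(roc, criterion)
        conf <- confusion_at_cutoff(scores[keep], labels[keep],
                                    opt$threshold)
        rocs[[g]][[m]] <- roc
        row <- data.frame(group = g, metric = m, n = sum(keep),
                          n_pos = sum(labels[keep]),
                          cutoff = opt$threshold,
                          sensitivity = conf$sensitivity,
                          specificity = conf$specificity,
                          ppv = conf$ppv, npv = conf$npv, auc = roc$auc,
                          estimable = TRUE)
      } else {
        rocs[[g]][[m]] <- NULL
        row <- data.frame(group = g, metric = m, n = sum(keep),
                          n_pos = sum(labels[keep], na.rm = TRUE),
                          cutoff = NA_real_, sensitivity = NA_real_,
                          specificity = NA_real_, ppv = NA_real_,
                          npv = NA_real_, auc = NA_real_,
                          estimable = FALSE)
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  structure(list(table = do.call(rbind, rows), rocs = rocs,
                 metrics = metrics, group = group,
                 tv_threshold = tv_threshold, criterion = criterion,
                 n = nrow(x)),
            class = "cutoff_analysis")
}

#' @export
print.cutoff_analysis <- function(x, ...) {
  cat(sprintf(
    "<cutoff_analysis> %d records, %s cutoffs by %s (TV >= %g cm^3)\n",
    x$n, x$criterion, x$group, x$tv_threshold))
  print(coef(x))
  invisible(x)
}

#' @export
coef.cutoff_analysis <- function(object, ...) {
  tab <- object$table
  groups <- unique(tab$group)
  out <- matrix(NA_real_, nrow = length(groups),
                ncol = length(object$metrics),
                dimnames = list(groups, object$metrics))
  for (i in seq_len(nrow(tab))) out[tab$group[i], tab$metric[i]] <- tab$cutoff[i]
  out
}

#' @export
summary.cutoff_analysis <- function(object, ...) {
  structure(list(table = format_cutoff_table(object$table),
                 criterion = object$criterion,
                 tv_threshold = object$tv_threshold),
            class = "summary.cutoff_analysis")
}

#' @export
print.summary.cutoff_analysis <- function(x, ...) {
  cat(sprintf(
    "Optimal PSA-derivative cutoffs (%s criterion, TV >= %g cm^3):\n\n",
    x$criterion, x$tv_threshold))
  print(x$table, row.names = FALSE)
  invisible(x)
}

# Printed precisions of the cutoff table: cutoffs per metric (PSA 2 dp,
# PSAD 2 dp, PSAM 2 dp, PSAMD 3 dp), rates and AUC as percentages at 1 dp.
cutoff_digits <- function(metric) {
  ifelse(metric == "psamd", 3L, 2L)
}

format_cutoff_table <- function(tab) {
  out <- tab
  out$cutoff <- mapply(function(v, m) round(v, cutoff_digits(m)),
                       tab$cutoff, tab$metric)
  for (col in c("sensitivity", "specificity", "ppv", "npv", "auc")) {
    out[[col]] <- round(100 * tab[[col]], 1)
  }
  out
}

#' @export
predict.cutoff_analysis <- function(object, newdata, metric = "psad",
                                    type = c("class", "positive"), ...) {
  type <- match.arg(type)
  stopifnot(metric %in% object$metrics)
  x <- as.data.frame(newdata)
  tab <- object$table[object$table$metric == metric, ]
  cuts <- stats::setNames(tab$cutoff, tab$group)
  g <- if (object$group == ".group") rep("All", nrow(x)) else x[[object$group]]
  unknown <- !g %in% names(cuts)
  if (any(unknown))
    stop("no fitted cutoff for group(s): ",
         paste(unique(g[unknown]), collapse = ", "))
  pos <- x[[metric]] >= cuts[g]
  if (type == "positive") return(pos)
  if (!"tumor_volume" %in% names(x))
    stop("type = 'class' needs tumor_volume in newdata")
  truth <- classify_significant(x$tumor_volume, object$tv_threshold)
  factor(ifelse(pos & truth, "TP",
                ifelse(pos & !truth, "FP",
                       ifelse(!pos & truth, "FN", "TN"))),
         levels = c("TP", "FP", "TN", "FN"))
}

#' @export
plot.cutoff_analysis <- function(x, metric = "psad",
                                 col = seq_along(x$rocs), ...) {
  stopifnot(metric %in% x$metrics)
  first <- TRUE
  groups <- names(x$rocs)
  drawn <- character(0)
  for (i in seq_along(groups)) {
    roc <- x$rocs[[groups[i]]][[metric]]
    if (is.null(roc)) next
    plot(roc, add = !first, col = col[i], ...)
    drawn <- c(drawn, groups[i])
    first <- FALSE
  }
  title(main = sprintf("ROC of %s for TV >= %g cm^3", metric,
                       x$tv_threshold))
  legend("bottomright", legend = drawn,
         col = col[match(drawn, groups)], lty = 1, bty = "n")
  invisible(x)
}

#' Screening classification at a fixed published cutoff
#'
#' Labels every record TP / FP / TN / FN under the score >= cutoff
#' positive-call rule against significant tumor volume, and tabulates the
#' labels by BMI category and by prostate weight relative to the
#' within-group median — the scatter-plot reading of screening performance:
#' records above the cutoff with TV < 0.5 cm^3 are false positives, above
#' the cutoff with TV >= 0.5 cm^3 true positives.
#'
#' @param derived cohort through \code{\link{derive_all}}.
#' @param metric score column, e.g. "psad" (published cutoff 0.15) or
#'   "psamd" (published cutoff 0.012).
#' @param cutoff screening cutoff in metric units.
#' @param group stratifying column for the within-group median prostate
#'   weight split (default "race_ethnicity"); NULL uses the whole-cohort
#'   median.
#' @param tv_threshold significant tumor volume (default 0.5 cm^3).
#' @return object of class \code{screening_classification}: list with
#'   \code{labels} (factor per record), \code{by_bmi} and \code{by_pw}
#'   (count tables), \code{counts} (overall), \code{pw_median} (per
#'   group), \code{metric}, \code{cutoff}.
#' @export
screening_classification <- function(derived, metric, cutoff,
                                     group = "race_ethnicity",
                                     tv_threshold = 0.5) {
  x <- as.data.frame(derived)
  stopifnot(metric %in% names(x), "tumor_volume" %in% names(x))
  pos <- x[[metric]] >= cutoff
  truth <- classify_significant(x$tumor_volume, tv_threshold)
  labels <- factor(ifelse(pos & truth, "TP",
                          ifelse(pos & !truth, "FP",
                                 ifelse(!pos & truth, "FN", "TN"))),
                   levels = c("TP", "FP", "TN", "FN"))

  g <- if (is.null(group)) rep("All", nrow(x)) else as.character(x[[group]])
  pw_median <- tapply(x$prostate_weight, g, stats::median)
  pw_side <- factor(ifelse(x$prostate_weight <= pw_median[g],
                           "PW <= group median", "PW > group median"))

  by_bmi <- table(bmi = x$bmi_category, label = labels, useNA = "ifany")
  by_pw <- table(pw = pw_side, label = labels)
  structure(list(labels = labels, counts = table(labels),
                 by_bmi = by_bmi, by_pw = by_pw,
                 pw_median = pw_median, metric = metric, cutoff = cutoff,
                 tv_threshold = tv_threshold),
            class = "screening_classification")
}

#' @export
print.screening_classification <- function(x, ...) {
  cat(sprintf(
    "<screening_classification> %s >= %g calls positive (TV >= %g cm^3)\n",
    x$metric, x$cutoff, x$tv_threshold))
  print(x$counts)
  cat("\nBy prostate-weight side of the group median:\n")
  print(x$by_pw)
  invisible(x)
}
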