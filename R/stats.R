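# Descriptive and inferential statistics of the workflow: group summaries
# shaped like the cohort characteristic tables, two-group and omnibus
# comparisons, correlations (plain and age-partial), and the uni-/multi-
# variable linear association of tumor volume with each PSA derivative.
#
# Standard tests are delegated to base R (t.test, aov, chisq.test,
# cor.test, lm); every wrapper returns the same light result structure so
# the report layer can treat them uniformly.  No multiple-testing
# correction is applied anywhere; p <= 0.05 is flagged as significant in
# the report layer, matching the workflow's decision rule.

stat_result <- function(estimate, statistic, p_value, n, df, method) {
  structure(list(estimate = estimate, statistic = statistic,
                 p_value = p_value, n = n, df = df, method = method),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s\n", x$method))
  if (!is.null(x$estimate) && length(x$estimate) == 1 && !is.na(x$estimate))
    cat(sprintf("  estimate %.4g, ", x$estimate))
  else cat("  ")
  cat(sprintf("statistic %.4g, df %s, p = %.4g (n = %d)\n",
              x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p_value, x$n))
  invisible(x)
}

#' Per-group descriptive summaries
#'
#' Produces the mean / median (min, max) block for each continuous variable
#' and count (percentage) blocks for categorical variables, within each
#' level of a grouping variable — the layout of a cohort-characteristics
#' table.  Percentages are computed within the column of records whose
#' value is known; the number excluded for a missing value is reported per
#' variable.
#'
#' @param derived a cohort passed through \code{\link{derive_all}} (plain
#'   cohorts work for the raw variables).
#' @param grouping column name to stratify on: "race_ethnicity",
#'   "institution" or "bmi_category".
#' @param continuous,categorical variable names to summarise; defaults
#'   cover the standard table layout.
#' @return list with \code{continuous} (data.frame: group, variable, n,
#'   mean, median, min, max), \code{categorical} (data.frame: group,
#'   variable, level, count, percent) and \code{group_n} (named counts,
#'   with an "All" column first).
#' @export
summarize_groups <- function(derived,
                             grouping = c("race_ethnicity", "institution",
                                          "bmi_category"),
                             continuous = NULL, categorical = NULL) {
  grouping <- match.arg(grouping)
  x <- as.data.frame(derived)
  if (is.null(continuous)) {
    continuous <- intersect(c("age", "psa", "psad", "psam", "psamd",
                              "prostate_weight", "tumor_volume", "bmi"),
                            names(x))
  }
  if (is.null(categorical)) {
    categorical <- intersect(setdiff(c("bmi_category", "institution",
                                       "race_ethnicity"), grouping),
                             names(x))
  }
  g <- x[[grouping]]
  if (all(is.na(g))) stop("grouping variable '", grouping, "' is all NA")
  groups <- c(list(All = rep(TRUE, nrow(x))),
              lapply(split(seq_len(nrow(x)), g), function(i)
                seq_len(nrow(x)) %in% i))

  cont <- do.call(rbind, lapply(names(groups), function(gn) {
    sel <- groups[[gn]]
    do.call(rbind, lapply(continuous, function(v) {
      vals <- x[[v]][sel]
      vals <- vals[!is.na(vals)]
      data.frame(group = gn, variable = v, n = length(vals),
                 mean = if (length(vals)) mean(vals) else NA_real_,
                 median = if (length(vals)) stats::median(vals) else NA_real_,
                 min = if (length(vals)) min(vals) else NA_real_,
                 max = if (length(vals)) max(vals) else NA_real_)
    }))
  }))

  cat_rows <- do.call(rbind, lapply(names(groups), function(gn) {
    sel <- groups[[gn]]
    do.call(rbind, lapply(categorical, function(v) {
      vals <- x[[v]][sel]
      vals <- vals[!is.na(vals)]
      if (!length(vals)) return(NULL)
      tab <- table(vals)
      data.frame(group = gn, variable = v, level = names(tab),
                 count = as.integer(tab),
                 percent = 100 * as.integer(tab) / length(vals))
    }))
  }))

  n_g <- vapply(groups, sum, 0L)
  structure(list(continuous = cont, categorical = cat_rows,
                 group_n = n_g, grouping = grouping),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, digits = 3, ...) {
  cat(sprintf("<group_summary> by %s: %s\n", x$grouping,
              paste(sprintf("%s n=%d", names(x$group_n), x$group_n),
                    collapse = ", ")))
  cont <- x$continuous
  cont$mean <- signif(cont$mean, digits)
  cont$median <- signif(cont$median, digits)
  print(utils::head(cont, 20), row.names = FALSE)
  if (nrow(cont) > 20) cat("  ...\n")
  invisible(x)
}

#' Two-group and omnibus comparisons
#'
#' \code{assoc_ttest}: two-sided pooled-variance (classic Student) t test.
#' \code{assoc_anova}: one-way F test across 2+ groups, the omnibus
#' companion used when more than two race/ethnicity groups are compared at
#' once.  \code{assoc_chisq}: Pearson chi-square on an r x c count table,
#' without continuity correction.
#'
#' @param x,y numeric samples (each n >= 2, nondegenerate combined
#'   variance).
#' @return a \code{stat_result}.
#' @examples
#' assoc_ttest(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df 4
#' @export
assoc_ttest <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  if (stats::var(c(x - mean(x), y - mean(y))) == 0)
    stop("degenerate (zero within-group variance) samples")
  ht <- stats::t.test(x, y, var.equal = TRUE)
  stat_result(estimate = unname(diff(rev(ht$estimate))),
              statistic = unname(ht$statistic), p_value = ht$p.value,
              n = length(x) + length(y), df = unname(ht$parameter),
              method = "Student t test (pooled variance, two-sided)")
}

#' @rdname assoc_ttest
#' @param samples list of 2+ numeric vectors, or a numeric vector paired
#'   with \code{g}.
#' @param g optional grouping factor when \code{samples} is one vector.
#' @export
assoc_anova <- function(samples, g = NULL) {
  if (!is.null(g)) samples <- split(samples, g)
  samples <- lapply(samples, function(v) v[!is.na(v)])
  if (length(samples) < 2) stop("need at least two groups")
  if (any(vapply(samples, length, 0L) < 2)) stop("each group needs n >= 2")
  vals <- unlist(samples, use.names = FALSE)
  grp <- factor(rep(seq_along(samples), vapply(samples, length, 0L)))
  fit <- stats::aov(vals ~ grp)
  tab <- summary(fit)[[1]]
  stat_result(estimate = NA_real_, statistic = tab[1, "F value"],
              p_value = tab[1, "Pr(>F)"], n = length(vals),
              df = c(tab[1, "Df"], tab[2, "Df"]),
              method = "one-way ANOVA F test")
}

#' @rdname assoc_ttest
#' @param counts matrix of nonnegative counts with positive row/col sums.
#' @export
assoc_chisq <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all row and column sums must be positive")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  stat_result(estimate = NA_real_, statistic = unname(ht$statistic),
              p_value = ht$p.value, n = sum(counts),
              df = unname(ht$parameter),
              method = "Pearson chi-square (no continuity correction)")
}

#' Pearson and age-partial correlation
#'
#' \code{pearson_corr} is the plain product-moment correlation with the
#' t-based two-sided p-value.  \code{partial_corr} removes a covariate
#' (age, in this workflow) from both variables:
#' r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)),
#' with p from the t statistic on n - 3 degrees of freedom.  Equivalently
#' it is the correlation of the residuals after regressing x and y on z.
#'
#' @param x,y numeric vectors (n >= 3 for \code{pearson_corr}, n >= 4 for
#'   \code{partial_corr}); pairs with any NA are dropped.
#' @return a \code{stat_result} whose estimate is r.
#' @export
pearson_corr <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  stat_result(estimate = unname(ht$estimate), statistic = unname(ht$statistic),
              p_value = ht$p.value, n = length(x),
              df = unname(ht$parameter), method = "Pearson correlation")
}

#' @rdname pearson_corr
#' @param z covariate to partial out (age).
#' @export
partial_corr <- function(x, y, z) {
  keep <- !is.na(x) & !is.na(y) & !is.na(z)
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  n <- length(x)
  if (n < 4) stop("need n >= 4 complete triples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0)
    stop("zero variance: partial correlation undefined")
  r_xy <- stats::cor(x, y); r_xz <- stats::cor(x, z); r_yz <- stats::cor(y, z)
  denom <- (1 - r_xz^2) * (1 - r_yz^2)
  if (denom < 1e-12)
    stop("a variable is collinear with the covariate: partial correlation undefined")
  r <- (r_xy - r_xz * r_yz) / sqrt(denom)
  df <- n - 3
  tstat <- r * sqrt(df / (1 - r^2))
  stat_result(estimate = r, statistic = tstat,
              p_value = 2 * stats::pt(-abs(tstat), df), n = n, df = df,
              method = "partial correlation (one covariate removed)")
}

#' Linear association of tumor volume with a PSA derivative
#'
#' Ordinary least squares of tumor volume on one derivative, optionally
#' age-adjusted (the multivariable form adds age and nothing else).  Thin
#' wrapper over \code{\link[stats]{lm}} returning the slope block plus the
#' fit.
#'
#' @param derived cohort through \code{\link{derive_all}}.
#' @param metric predictor column: "psa", "psad", "psam" or "psamd".
#' @param adjust_age if TRUE, fit tumor_volume ~ metric + age.
#' @param response response column (default "tumor_volume").
#' @return list with \code{coefficients} (data.frame: term, estimate, se,
#'   t, p), \code{r_squared}, \code{n}, and the underlying \code{lm} fit.
#' @export
tv_linear_model <- function(derived, metric, adjust_age = FALSE,
                            response = "tumor_volume") {
  x <- as.data.frame(derived)
  stopifnot(metric %in% names(x), response %in% names(x))
  rhs <- if (adjust_age) paste(metric, "+ age") else metric
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = x, na.action = stats::na.omit)
  sm <- summary(fit)$coefficients
  list(coefficients = data.frame(term = rownames(sm),
                                 estimate = sm[, "Estimate"],
                                 se = sm[, "Std. Error"],
                                 t = sm[, "t value"],
                                 p = sm[, "Pr(>|t|)"],
                                 row.names = NULL),
       r_squared = summary(fit)$r.squared,
       n = length(stats::residuals(fit)),
       fit = fit)
}
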