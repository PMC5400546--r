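# ROC construction, AUC, upper-left optimal cutoff, confusion rates, and
# the fixed-specificity sensitivity comparison.
#
# Positive-call convention, used everywhere in the package: a record screens
# POSITIVE when its score is >= the cutoff, so a published cutoff value
# itself screens positive.  Thresholds are evaluated at the observed score
# values (no midpoints), which makes every operating point reproducible on
# discrete data; ties share one operating point.

#' Build a ROC curve
#'
#' One operating point per distinct observed score (calling positive when
#' score >= threshold), plus the degenerate all-negative point at +Inf.  By
#' construction sensitivity and false-positive rate are non-increasing in
#' the threshold and the curve spans (1, 1) down to (0, 0) in (FPR,
#' sensitivity) space.  The AUC is the trapezoidal area, which on this
#' construction equals the pair-counting concordance statistic
#' P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param scores numeric vector of metric values (e.g. PSAD).
#' @param labels logical vector: TRUE for positive (significant tumor
#'   volume), FALSE for negative.  Both classes must be present.
#' @return object of class \code{psa_roc}: list with \code{points} (a
#'   data.frame of threshold, sensitivity, specificity, fpr), \code{auc},
#'   \code{n_pos}, \code{n_neg}.
#' @examples
#' r <- build_roc(c(1, 2, 2, 3), c(FALSE, TRUE, FALSE, TRUE))
#' r$auc  # 0.875
#' @export
build_roc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), is.numeric(scores))
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L) stop("no positive records: ROC curve is undefined")
  if (n_neg == 0L) stop("no negative records: ROC curve is undefined")

  # tp[i] = positives with score >= thresholds[i]: sort descending once and
  # take cumulative counts at the last index of each distinct score block.
  uniq <- sort(unique(scores))
  thresholds <- c(uniq, Inf)
  ord <- order(scores, decreasing = TRUE)
  l_sorted <- labels[ord]
  cum_tp <- cumsum(l_sorted)
  cum_fp <- cumsum(!l_sorted)
  # number of records with score >= uniq[k]
  n_ge <- rev(cumsum(rev(tabulate(match(scores, uniq), length(uniq)))))
  tp <- c(cum_tp[n_ge], 0)
  fp <- c(cum_fp[n_ge], 0)
  sens <- tp / n_pos
  fpr <- fp / n_neg

  points <- data.frame(threshold = thresholds, sensitivity = sens,
                       specificity = 1 - fpr, fpr = fpr)
  auc <- trapezoid_auc(points$fpr, points$sensitivity)
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "psa_roc")
}

# Area under sensitivity vs FPR by the trapezoidal rule.  Ties in FPR
# (vertical curve segments) must be ordered by sensitivity too, or the
# polygon self-intersects and the area is wrong.
trapezoid_auc <- function(fpr, sens) {
  o <- order(fpr, sens)
  x <- fpr[o]
  y <- sens[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.psa_roc <- function(x, ...) {
  cat(sprintf("<psa_roc> %d operating points, %d pos / %d neg, AUC %.3f\n",
              nrow(x$points), x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' @export
plot.psa_roc <- function(x, add = FALSE, ...) {
  if (!add) {
    plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "1 - specificity",
         ylab = "Sensitivity", asp = 1)
    abline(0, 1, lty = 3, col = "grey60")
  }
  o <- order(x$points$fpr)
  lines(x$points$fpr[o], x$points$sensitivity[o], type = "s", ...)
  invisible(x)
}

#' @rdname build_roc
#' @param roc a \code{psa_roc} object.
#' @export
roc_auc <- function(roc) {
  stopifnot(inherits(roc, "psa_roc"))
  roc$auc
}

#' Optimal cutoff at the most upper-left point of the ROC curve
#'
#' Selects the threshold whose operating point minimises the Euclidean
#' distance from (FPR, sensitivity) to the ideal corner (0, 1).  Ties are
#' broken toward higher specificity, then toward the higher threshold.  The
#' alternative criterion \code{"youden"} maximises sensitivity +
#' specificity - 1 (same tie-breaks).
#'
#' @param roc a \code{psa_roc}.
#' @param criterion "upper_left" (default) or "youden".
#' @return one-row data.frame: threshold, sensitivity, specificity,
#'   distance (to the corner), youden.
#' @export
optimal_cutoff <- function(roc, criterion = c("upper_left", "youden")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(roc, "psa_roc"))
  p <- roc$points
  d <- sqrt(p$fpr^2 + (1 - p$sensitivity)^2)
  j <- p$sensitivity + p$specificity - 1
  key <- if (criterion == "upper_left") d else -j
  # minimal key with a numerical tie tolerance (distances computed from
  # rational sens/spec can differ at machine precision only), then the
  # tie-breaks: higher specificity, then higher threshold
  tied <- which(key <= min(key) + 1e-12)
  best <- tied[order(-p$specificity[tied], -p$threshold[tied])[1]]
  data.frame(threshold = p$threshold[best],
             sensitivity = p$sensitivity[best],
             specificity = p$specificity[best],
             distance = d[best], youden = j[best])
}

#' Confusion-matrix rates at a fixed cutoff
#'
#' Applies the score >= cutoff positive-call rule and returns the four
#' counts and the four rates.  Rates with a zero denominator (e.g. PPV with
#' no predicted positives) are NA, never 0.
#'
#' @param scores,labels as in \code{\link{build_roc}}.
#' @param cutoff the screening cutoff in score units.
#' @return list with \code{tp, fp, tn, fn, sensitivity, specificity, ppv,
#'   npv, n}.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  pos_call <- scores >= cutoff
  tp <- sum(pos_call & labels)
  fp <- sum(pos_call & !labels)
  fn <- sum(!pos_call & labels)
  tn <- sum(!pos_call & !labels)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = rate(tp, tp + fn),
       specificity = rate(tn, tn + fp),
       ppv = rate(tp, tp + fp),
       npv = rate(tn, tn + fn),
       n = length(scores))
}

#' Sensitivity at a fixed specificity
#'
#' Returns the sensitivity of the operating point with the smallest
#' achievable specificity at or above the target (conservative attainment:
#' the specificity constraint is met, not interpolated).  If only the
#' degenerate all-negative point satisfies the constraint the sensitivity
#' is 0.
#'
#' @param roc a \code{psa_roc}.
#' @param spec_target required specificity (default 0.80).
#' @return list with \code{sensitivity}, \code{specificity},
#'   \code{threshold} of the attaining point.
#' @export
sensitivity_at_fixed_specificity <- function(roc, spec_target = 0.80) {
  stopifnot(inherits(roc, "psa_roc"))
  p <- roc$points
  ok <- p$specificity >= spec_target
  p <- p[ok, , drop = FALSE]
  # smallest attaining specificity; among ties, the most sensitive point
  best <- order(p$specificity, -p$sensitivity, p$threshold)[1]
  list(sensitivity = p$sensitivity[best],
       specificity = p$specificity[best],
       threshold = p$threshold[best])
}

#' Paired bootstrap comparison of sensitivity at fixed specificity
#'
#' Compares two scoring metrics on the same records: for each bootstrap
#' resample of records (with replacement, keeping the pairing) it rebuilds
#' both ROC curves and takes the difference in sensitivity at the fixed
#' specificity.  Reports the observed difference, the percentile confidence
#' interval and a two-sided percentile-bootstrap p-value
#' (2 min(P(diff* <= 0), P(diff* >= 0)), capped at 1).  Resamples in which a
#' class disappears are redrawn.
#'
#' @param scores_a,scores_b paired numeric scores on identical records.
#' @param labels logical outcome per record.
#' @param spec_target fixed specificity (default 0.80).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed (mandatory: the comparison is resampling-based).
#' @param conf confidence level of the percentile interval (default 0.95).
#' @return list with \code{diff} (a - b), \code{sens_a}, \code{sens_b},
#'   \code{p_value}, \code{ci}, \code{n_boot}, \code{method}.
#' @export
compare_sensitivity_bootstrap <- function(scores_a, scores_b, labels,
                                          spec_target = 0.80,
                                          n_boot = 2000, seed,
                                          conf = 0.95) {
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  if (missing(seed)) stop("seed is required for the bootstrap comparison")
  labels <- as.logical(labels)
  n <- length(labels)
  sens_at <- function(sa, sb, lab) {
    c(sensitivity_at_fixed_specificity(build_roc(sa, lab),
                                       spec_target)$sensitivity,
      sensitivity_at_fixed_specificity(build_roc(sb, lab),
                                       spec_target)$sensitivity)
  }
  obs <- sens_at(scores_a, scores_b, labels)
  set.seed(seed)
  diffs <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(labels[idx]) && any(!labels[idx])) break
    }
    s <- sens_at(scores_a[idx], scores_b[idx], labels[idx])
    diffs[b] <- s[1] - s[2]
  }
  p <- min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0)))
  alpha <- 1 - conf
  list(diff = obs[1] - obs[2], sens_a = obs[1], sens_b = obs[2],
       p_value = p,
       ci = unname(stats::quantile(diffs, c(alpha / 2, 1 - alpha / 2))),
       n_boot = n_boot,
       method = "paired percentile bootstrap of sensitivity at fixed specificity")
}
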