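# Independent oracles and fixture builders shared across the suite.

# Concordance statistic by exhaustive pair enumeration:
# P(score_pos > score_neg) + 0.5 P(tie) over all pos x neg pairs.
concordance_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Upper-left optimal cutoff by brute force: evaluate every candidate
# threshold (each observed score plus +Inf) by direct counting and minimize
# the Euclidean distance to (FPR, sens) = (0, 1); ties to higher
# specificity, then higher threshold.
upper_left_oracle <- function(scores, labels) {
  cands <- c(sort(unique(scores)), Inf)
  best <- NULL
  for (t in cands) {
    call_pos <- scores >= t
    sens <- sum(call_pos & labels) / sum(labels)
    spec <- sum(!call_pos & !labels) / sum(!labels)
    d <- sqrt((1 - spec)^2 + (1 - sens)^2)
    cand <- list(threshold = t, sens = sens, spec = spec, d = d)
    if (is.null(best) ||
        d < best$d - 1e-12 ||
        (abs(d - best$d) <= 1e-12 &&
         (spec > best$spec + 1e-12 ||
          (abs(spec - best$spec) <= 1e-12 && t > best$threshold)))) {
      best <- cand
    }
  }
  best
}

# Minimal valid cohort data.frame; override any column via ...
make_cohort_df <- function(n = 3, ...) {
  base <- data.frame(
    id = if (n > 0) paste0("P", seq_len(n)) else character(0),
    age = rep(60, n),
    race_ethnicity = rep("NHW", n),
    race_code = rep("White", n),
    surname = rep(NA_character_, n),
    institution = rep("JHU", n),
    height = rep(1.75, n),
    weight = rep(80, n),
    psa = rep(4.4, n),
    prostate_weight = rep(44.9, n),
    tumor_grid_mm2 = rep(NA_real_, n),
    tumor_volume = rep(0.4, n),
    stringsAsFactors = FALSE)
  over <- list(...)
  for (k in names(over)) base[[k]] <- over[[k]]
  base
}

# Random small ROC instance with both classes present.
random_roc_instance <- function(max_n = 10, tie_prob = 0.5) {
  n <- sample(2:max_n, 1)
  scores <- if (stats::runif(1) < tie_prob) {
    sample(1:4, n, replace = TRUE)  # heavy ties
  } else {
    round(stats::runif(n), 3)
  }
  labels <- as.logical(sample(0:1, n, replace = TRUE))
  if (all(labels)) labels[1] <- FALSE
  if (!any(labels)) labels[1] <- TRUE
  list(scores = as.numeric(scores), labels = labels)
}
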