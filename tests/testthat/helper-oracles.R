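# Independent oracles and small fixtures used across the suite.

# Brute-force pair-counting AUC: P(score_pos > score_neg) + 0.5 * ties.
# `labels` must be 0/1.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exhaustive scan oracle for the sens^2+spec^2-optimal threshold:
# evaluates every achievable operating point via candidate cuts between
# consecutive distinct scores (plus the two extremes), ties to the
# lowest threshold.
scan_threshold <- function(scores, labels) {
  y <- as.integer(labels == 1)
  s <- sort(unique(scores))
  gap <- if (length(s) > 1) min(diff(s)) else 1
  cand <- c(s[1] - gap / 2,
            if (length(s) > 1) (s[-length(s)] + s[-1]) / 2,
            s[length(s)] + gap / 2)
  best_t <- NA; best_c <- -Inf
  for (t in sort(cand)) {
    sens <- mean(scores[y == 1] >= t)
    spec <- mean(scores[y == 0] < t)
    crit <- sens^2 + spec^2
    if (crit > best_c + 1e-12) { best_c <- crit; best_t <- t }
  }
  best_t
}

# A small, fast cohort configuration for module tests.
tiny_config <- function(seed = 1L, ...) {
  simulation_config(n_cnt = 12L, n_pd = 8L, n_prod = 6L, seed = seed, ...)
}

# Six consistent connectomes (both timepoints x three metrics) for one
# subject, optionally with a given |change| on a chosen edge cell.
toy_connectome_set <- function(subject_id = "s01", delta_cell = NULL,
                               delta = 0, metric = "streamline_count") {
  base <- list(
    streamline_count = {
      m <- matrix(10, 16, 16); diag(m) <- 0; m
    },
    mean_fa = {
      m <- matrix(0.4, 16, 16); diag(m) <- 0; m
    },
    mean_md = {
      m <- matrix(0.7e-3, 16, 16); diag(m) <- 0; m
    })
  fu <- base
  if (!is.null(delta_cell)) {
    i <- delta_cell[1]; j <- delta_cell[2]
    fu[[metric]][i, j] <- fu[[metric]][i, j] + delta
    fu[[metric]][j, i] <- fu[[metric]][i, j]
  }
  out <- list()
  for (met in connectome_metrics()) {
    out[[paste0("baseline.", met)]] <-
      validate_connectome(base[[met]], met, subject_id, "baseline")
    out[[paste0("followup.", met)]] <-
      validate_connectome(fu[[met]], met, subject_id, "followup")
  }
  out
}
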