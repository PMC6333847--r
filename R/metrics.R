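#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive subject scores above a randomly chosen negative one, with
#' ties counting one half.  Computed via mid-ranks, which is exactly the
#' pair-counting statistic.
#'
#' @param scores Numeric scores (higher = more disease-like).
#' @param labels Binary labels (positive class = 1 / "PD" / second
#'   level).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  y <- as_binary(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve
#'
#' Enumerates every achievable operating point.  The decision rule is
#' "positive if score >= threshold"; candidate thresholds are the
#' midpoints between consecutive distinct scores (so a returned threshold
#' sits in the middle of the gap it cuts), plus one below the minimum
#' (everything positive) and one above the maximum (everything negative).
#' The trapezoidal area under the returned points equals [auc()] exactly,
#' including the half credit for ties.
#'
#' @inheritParams auc
#' @return A `roc_curve` data frame with columns `threshold`, `fpr`,
#'   `tpr`, `sensitivity`, `specificity`, ordered from the (0,0) corner
#'   to the (1,1) corner.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  s <- sort(unique(scores))
  gap <- if (length(s) > 1L) min(diff(s)) else 1
  cand <- c(s[1] - gap / 2,
            if (length(s) > 1L) (s[-length(s)] + s[-1]) / 2,
            s[length(s)] + gap / 2)
  cand <- sort(cand, decreasing = TRUE)   # (0,0) corner first
  tpr <- vapply(cand, function(t) sum(scores[y == 1L] >= t) / n1,
                numeric(1))
  fpr <- vapply(cand, function(t) sum(scores[y == 0L] >= t) / n0,
                numeric(1))
  out <- data.frame(threshold = cand, fpr = fpr, tpr = tpr,
                    sensitivity = tpr, specificity = 1 - fpr)
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Trapezoidal area under a ROC curve
#' @param roc A [roc_curve()] result.
#' @return Area in \[0, 1\]; equals [auc()] on the same data.
#' @export
trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
}

#' Bootstrap percentile confidence interval for the AUC
#'
#' Nonparametric bootstrap of the prediction-label pairs: each of
#' `n_reps` replicates resamples `ceiling(keep_frac * n)` pairs with
#' replacement (a replicate that draws a single class is redrawn),
#' recomputes the AUC, and (for the ROC band) an interpolated ROC on a
#' fixed FPR grid.  Reported interval: the 5th and 95th percentiles of
#' the replicate AUCs, i.e. a 90% percentile interval.
#'
#' @inheritParams auc
#' @param n_reps Bootstrap repetitions (default 1000).
#' @param keep_frac Fraction of predictions kept per replicate (default
#'   0.8).
#' @param seed Integer seed.
#' @param fpr_grid FPR grid for the ROC band (default 101 points).
#' @return List: `ci_low`, `ci_high`, `replicates` (the n_reps AUC
#'   values), `roc_band` (data frame: fpr, tpr_low, tpr_high), `n_reps`,
#'   `keep_frac`.
#' @export
bootstrap_ci <- function(scores, labels, n_reps = 1000L, keep_frac = 0.8,
                         seed = 1L, fpr_grid = seq(0, 1, length.out = 101)) {
  y <- as_binary(labels)
  n <- length(scores)
  if (sum(y == 1L) < 4L || sum(y == 0L) < 4L)
    warning("fewer than 4 subjects in a class: bootstrap CI unstable")
  m <- ceiling(keep_frac * n)
  set.seed(seed)
  reps <- numeric(n_reps)
  band <- matrix(NA_real_, n_reps, length(fpr_grid))
  for (b in seq_len(n_reps)) {
    repeat {
      idx <- sample.int(n, m, replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
    }
    sb <- scores[idx]; yb <- y[idx]
    reps[b] <- auc(sb, yb)
    rc <- roc_curve(sb, yb)
    band[b, ] <- stats::approx(rc$fpr, rc$tpr, xout = fpr_grid,
                               ties = max, rule = 2)$y
  }
  qs <- stats::quantile(reps, c(0.05, 0.95), names = FALSE)
  list(ci_low = qs[1], ci_high = qs[2], replicates = reps,
       roc_band = data.frame(
         fpr = fpr_grid,
         tpr_low = apply(band, 2, stats::quantile, probs = 0.05),
         tpr_high = apply(band, 2, stats::quantile, probs = 0.95)),
       n_reps = n_reps, keep_frac = keep_frac)
}

#' ROC-optimal decision threshold
#'
#' The threshold maximizing sensitivity^2 + specificity^2 over all
#' operating points of the curve.  Ties are broken toward the lower
#' threshold (higher sensitivity), matching a screening use-case.  For a
#' perfectly separating score the returned value is the midpoint of the
#' separating gap.
#'
#' @param roc A [roc_curve()] result.
#' @return The chosen threshold (numeric scalar).
#' @export
optimal_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  crit <- roc$sensitivity^2 + roc$specificity^2
  best <- which(crit >= max(crit) - 1e-12)
  min(roc$threshold[best])
}

#' Confusion-matrix metrics at a threshold
#'
#' Classifies positive where `score >= threshold` and reports
#' sensitivity, specificity, balanced accuracy ((sens + spec) / 2) and
#' Cohen's kappa ((p_o - p_e) / (1 - p_e)).
#'
#' @inheritParams auc
#' @param threshold Decision threshold.
#' @return List: `sensitivity`, `specificity`, `balanced_accuracy`,
#'   `kappa`, and the `confusion` counts (tp, fn, tn, fp).
#' @export
classification_metrics <- function(scores, labels, threshold) {
  y <- as_binary(labels)
  if (threshold < 0 || threshold > 1)
    warning("threshold ", format(threshold), " outside [0, 1]")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L); fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L); fp <- sum(pred == 1L & y == 0L)
  n <- length(y)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (abs(1 - pe) < 1e-15) 0 else (po - pe) / (1 - pe)
  list(sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2, kappa = kappa,
       confusion = c(tp = tp, fn = fn, tn = tn, fp = fp))
}

# Firth (Jeffreys-penalized) logistic regression; used as fallback when
# the plain ML fit separates. X includes an intercept column.
firth_logistic <- function(X, y, maxit = 100, tol = 1e-8) {
  p <- ncol(X)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * w
    info <- crossprod(X, XW)
    info_inv <- solve(info)
    h <- rowSums((X %*% info_inv) * XW)
    u <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- drop(info_inv %*% u)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(info_inv))
  list(coef = beta, se = se)
}

#' Covariate-adjusted significance of a progression score
#'
#' Fits a logistic regression of the binary group on the progression
#' score, age and gender, and returns the two-sided Wald p-value of the
#' score coefficient.  If the maximum-likelihood fit separates perfectly
#' (non-converged or exploding coefficients), a Jeffreys-penalized
#' (Firth) fit is used instead and flagged in the result.
#'
#' @inheritParams auc
#' @param age Numeric vector of ages.
#' @param gender Factor/character of genders (any two-level coding).
#' @return List: `p` (Wald p-value of the score term), `coef` (score
#'   coefficient), `se`, `method` ("ml" or "firth").
#' @export
covariate_adjusted_p <- function(scores, labels, age, gender) {
  y <- as_binary(labels)
  if (stats::sd(scores) < 1e-12)
    stop("degenerate input: score is constant")
  n <- length(y)
  if (n <= 5L) stop("too few subjects for a 3-covariate model")
  g <- as.integer(factor(gender)) - 1L
  X <- cbind(1, scores, age, g)
  colnames(X) <- c("(Intercept)", "score", "age", "gender")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  coefs <- fit$coefficients
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  se <- tryCatch(sqrt(diag(solve(crossprod(X, X * w)))),
                 error = function(e) rep(Inf, ncol(X)))
  # perfect separation: non-convergence, exploding SEs, or all fitted
  # probabilities at the data
  separated <- !fit$converged || !all(is.finite(se)) || se[2] > 50 ||
    all(abs(y - mu) < 1e-8)
  if (!separated) {
    zval <- coefs["score"] / se[2]
    list(p = 2 * stats::pnorm(-abs(zval)), coef = unname(coefs["score"]),
         se = unname(se[2]), method = "ml")
  } else {
    ff <- firth_logistic(X, y)
    zval <- ff$coef[2] / ff$se[2]
    list(p = 2 * stats::pnorm(-abs(zval)), coef = ff$coef[2],
         se = ff$se[2], method = "firth")
  }
}

#' Cross-sectional or longitudinal evaluation of a scalar marker
#'
#' Treats a single clinical scale (a cross-sectional value, or a
#' follow-up minus baseline difference) as the classification score.
#' Since scales differ in orientation (e.g. motor scores increase with
#' disease, cognitive scores decrease), the marker is auto-flipped when
#' needed so the reported AUC is >= 0.5, and the flip is recorded.
#'
#' @param values Numeric marker values, one per subject.
#' @param labels Binary group labels.
#' @param age,gender Optional covariates; when both are given the
#'   p-value is covariate-adjusted via [covariate_adjusted_p()],
#'   otherwise it is the unadjusted Wald p of a univariate logistic fit.
#' @return List: `auc`, `p`, `flipped` (logical).
#' @export
scalar_marker_eval <- function(values, labels, age = NULL, gender = NULL) {
  if (stats::sd(values) < 1e-12) stop("constant marker")
  a <- auc(values, labels)
  flipped <- a < 0.5
  v <- if (flipped) -values else values
  if (flipped) a <- 1 - a
  p <- if (!is.null(age) && !is.null(gender)) {
    covariate_adjusted_p(v, labels, age, gender)$p
  } else {
    y <- as_binary(labels)
    fit <- suppressWarnings(stats::glm(y ~ v, family = stats::binomial()))
    stats::coef(summary(fit))["v", "Pr(>|z|)"]
  }
  list(auc = a, p = p, flipped = flipped)
}

#' Full evaluation report for a set of progression scores
#'
#' Bundles the discrimination analysis for one contrast (e.g. Control vs
#' PD out-of-fold scores, or Control vs PROD with model-averaged scores):
#' ROC curve, AUC with bootstrap 5th-95th percentile CI, the
#' sens^2+spec^2-optimal threshold with its confusion metrics, the same
#' metrics at the conventional 0.5 threshold, and the covariate-adjusted
#' p-value when age/gender are supplied.
#'
#' @inheritParams auc
#' @param age,gender Optional covariates for the adjusted p-value.
#' @param n_boot Bootstrap repetitions.
#' @param seed Integer seed for the bootstrap.
#' @return An `evaluation_report` list: `auc`, `ci_low`, `ci_high`,
#'   `chosen_threshold`, `metrics_optimal`, `metrics_05`, `adjusted_p`,
#'   `n_pos`, `n_neg`, `roc`, `bootstrap`, `settings`.
#' @export
evaluate_scores <- function(scores, labels, age = NULL, gender = NULL,
                            n_boot = 1000L, seed = 1L) {
  y <- as_binary(labels)
  roc <- roc_curve(scores, y)
  a <- auc(scores, y)
  bs <- bootstrap_ci(scores, y, n_reps = n_boot, seed = seed)
  thr <- optimal_threshold(roc)
  rep <- list(
    auc = a, ci_low = bs$ci_low, ci_high = bs$ci_high,
    chosen_threshold = thr,
    metrics_optimal = classification_metrics(scores, y, thr),
    metrics_05 = classification_metrics(scores, y, 0.5),
    adjusted_p = if (!is.null(age) && !is.null(gender))
      covariate_adjusted_p(scores, y, age, gender)$p else NA_real_,
    n_pos = sum(y == 1L), n_neg = sum(y == 0L),
    roc = roc, bootstrap = bs,
    settings = list(n_boot = n_boot, keep_frac = 0.8, seed = seed,
                    ci = "percentile 5th-95th")
  )
  class(rep) <- "evaluation_report"
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> AUC %.3f [CI 5th-95th pct: %.3f-%.3f]\n",
              x$auc, x$ci_low, x$ci_high))
  m <- x$metrics_optimal
  cat(sprintf("  threshold %.3f: sens %.3f, spec %.3f, bal.acc %.3f, kappa %.3f\n",
              x$chosen_threshold, m$sensitivity, m$specificity,
              m$balanced_accuracy, m$kappa))
  if (!is.na(x$adjusted_p))
    cat(sprintf("  covariate-adjusted p = %.3g\n", x$adjusted_p))
  invisible(x)
}
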