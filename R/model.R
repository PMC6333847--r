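#' Specify a progression classifier
#'
#' Fixed-hyperparameter model menu for the Control-vs-PD progression
#' classifier.  Hyperparameters are never tuned: the logistic families
#' use inverse-regularization C = 1 (mapped to the coordinate-descent
#' lambda as 1/(n*C)), the elastic net mixes L1/L2 at 0.5, the linear SVM
#' uses cost 1 with squared-hinge loss, and the random forest grows 100
#' Gini trees with mtry = floor(sqrt(p)).  Default feature scaling is a
#' per-training-fold z-score so that count-scale features do not dominate
#' the penalty over FA/MD-scale features; `scaling = "none"` reproduces a
#' raw-feature run.
#'
#' @param family One of `"logreg_l1"`, `"logreg_l2"`, `"elastic_net"`,
#'   `"linear_svm"`, `"random_forest"`.
#' @param scaling `"trainfold_zscore"` (default) or `"none"`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(family = c("logreg_l1", "logreg_l2", "elastic_net",
                                  "linear_svm", "random_forest"),
                       scaling = c("trainfold_zscore", "none")) {
  family <- match.arg(family)
  scaling <- match.arg(scaling)
  hyper <- switch(family,
    logreg_l1 = list(C = 1, alpha = 1),
    logreg_l2 = list(C = 1, alpha = 0),
    elastic_net = list(C = 1, alpha = 0.5),
    linear_svm = list(C = 1),
    random_forest = list(n_trees = 100L, min_node = 2L, max_depth = 8L))
  structure(list(family = family, scaling = scaling, hyper = hyper),
            class = "model_spec")
}

# Normalize labels to 0/1 with the positive (disease) class = 1.
# Accepts 0/1 numerics, logicals, or a two-level factor/character where
# "PD" (if present) or the second sorted level is positive.
as_binary <- function(labels, positive = NULL) {
  if (is.numeric(labels) && all(labels %in% c(0, 1)))
    return(structure(as.integer(labels), levels = c("0", "1")))
  if (is.logical(labels))
    return(structure(as.integer(labels), levels = c("FALSE", "TRUE")))
  lv <- if (is.factor(labels)) levels(droplevels(labels)) else
    sort(unique(as.character(labels)))
  if (length(lv) != 2L)
    stop("labels must have exactly two classes, got: ",
         paste(lv, collapse = ", "))
  if (is.null(positive)) positive <- if ("PD" %in% lv) "PD" else lv[2]
  structure(as.integer(as.character(labels) == positive),
            levels = c(setdiff(lv, positive), positive))
}

#' Stratified k-fold assignment
#'
#' Partitions subjects into k folds preserving the class balance: each
#' fold's per-class count differs from an exact proportional split by at
#' most one subject.  With 30 controls + 21 patients and k = 21 (the
#' maximum admitted by the smaller class) every test fold holds 2 or 3
#' subjects.  Deterministic given `seed`.
#'
#' @param labels Binary class labels, one per subject.
#' @param k Number of folds (2 <= k <= n).
#' @param seed Integer seed.
#' @return Integer vector of fold indices in 1..k.
#' @export
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("need 2 <= k <= n (n = ", n, ", k = ", k, ")")
  y <- as_binary(labels)
  if (length(unique(y)) < 2L) stop("single-class input")
  set.seed(seed)
  fold <- integer(n)
  loads <- integer(k)   # total subjects per fold so far
  for (cl in c(0L, 1L)) {
    idx <- which(y == cl)
    idx <- if (length(idx) > 1L) sample(idx) else idx
    q <- length(idx) %/% k; r <- length(idx) %% k
    # the r extra members go to the currently least-loaded folds, so
    # total fold sizes stay within one of each other
    counts <- rep(q, k)
    if (r > 0L) {
      extra <- order(loads, stats::runif(k))[seq_len(r)]
      counts[extra] <- counts[extra] + 1L
    }
    fold[idx] <- rep(seq_len(k), counts)
    loads <- loads + counts
  }
  fold
}

cols_constant <- function(x) {
  apply(x, 2, function(col) max(col) - min(col) < 1e-12)
}

fit_scaling <- function(x, scaling) {
  if (scaling == "none")
    return(list(center = rep(0, ncol(x)), scale = rep(1, ncol(x))))
  ctr <- colMeans(x)
  sc <- apply(x, 2, stats::sd)
  sc[sc < 1e-12] <- 1   # constant features stay at zero after centering
  list(center = ctr, scale = sc)
}

apply_scaling <- function(x, sc) {
  sweep(sweep(x, 2, sc$center, "-"), 2, sc$scale, "/")
}

#' Train one fold model
#'
#' Fits the specified classifier on a training fold.  Scaling statistics
#' (when `trainfold_zscore`) come from the training fold only, so no
#' information leaks from test or independent subjects.  Linear families
#' expose a 360-weight vector (on the scaled feature space) interrogated
#' by the permutation relevance test; the random forest exposes Gini
#' importances instead.
#'
#' @param features Numeric matrix (subjects x features).
#' @param labels Binary labels (see Details of [stratified_folds()]).
#' @param spec A [model_spec()].
#' @param seed Seed for stochastic families (random forest); ignored by
#'   the deterministic linear fits.
#' @return A `trained_model` with elements `weights`, `intercept`,
#'   `family`, `scaling`, and (random forest only) `forest`,
#'   `importance`.
#' @export
train_fold <- function(features, labels, spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), is.matrix(features))
  y <- as_binary(labels)
  if (length(y) != nrow(features))
    stop("labels/features row mismatch")
  if (any(!is.finite(features))) stop("non-finite feature values")
  if (length(unique(y)) < 2L) stop("single-class training fold")
  sc <- fit_scaling(features, spec$scaling)
  xs <- apply_scaling(features, sc)
  n <- nrow(xs)
  fam <- spec$family
  if (fam %in% c("logreg_l1", "logreg_l2", "elastic_net")) {
    forest <- NULL; importance <- NULL
    if (all(cols_constant(xs))) {
      # every feature constant: the regularized fit has zero weights and
      # the intercept carries the class prior
      w <- numeric(ncol(xs))
      b <- stats::qlogis(mean(y))
    } else {
      lambda <- 1 / (n * spec$hyper$C)
      # glmnet warns when a class has < 8 observations, routine at
      # leave-2-or-3-out fold sizes; the fit itself is fine
      fit <- suppressWarnings(
        glmnet::glmnet(xs, y, family = "binomial",
                       alpha = spec$hyper$alpha, lambda = lambda,
                       standardize = FALSE))
      w <- as.numeric(fit$beta[, 1])
      b <- as.numeric(fit$a0[1])
    }
  } else if (fam == "linear_svm") {
    sv <- svm_fit(xs, y, C = spec$hyper$C)
    w <- sv$w; b <- sv$b
    forest <- NULL; importance <- NULL
  } else { # random_forest
    rf <- rf_fit(xs, y, n_trees = spec$hyper$n_trees,
                 min_node = spec$hyper$min_node,
                 max_depth = spec$hyper$max_depth, seed = seed)
    w <- NULL; b <- NULL
    forest <- rf$trees; importance <- rf$importance
  }
  structure(list(weights = w, intercept = b, family = fam,
                 scaling = sc, spec = spec, forest = forest,
                 importance = importance,
                 levels = attr(y, "levels")),
            class = "trained_model")
}

#' Predict progression scores from a trained model
#'
#' Returns scores in \[0, 1\]: predicted probability of the disease class
#' for the logistic families and the random forest; for the linear SVM
#' the margin is squashed through the logistic function.
#'
#' @param object A `trained_model`.
#' @param newdata Feature matrix with the same columns used in training.
#' @param ... Unused.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
predict.trained_model <- function(object, newdata, ...) {
  if (ncol(newdata) != length(object$scaling$center))
    stop("feature-dimension mismatch: model has ",
         length(object$scaling$center), ", data has ", ncol(newdata))
  xs <- apply_scaling(newdata, object$scaling)
  if (object$family == "random_forest")
    return(rf_predict(object$forest, xs))
  margin <- drop(xs %*% object$weights) + object$intercept
  stats::plogis(margin)
}

# ---- linear SVM (squared hinge, primal, L-BFGS) ------------------------
# No SVM package ships with this environment, so the linear SVM is a
# direct primal minimizer of 0.5*||w||^2 + C * sum(max(0, 1 - y*m)^2),
# the default loss of common linear-SVM implementations.
svm_fit <- function(x, y01, C = 1) {
  y <- ifelse(y01 == 1L, 1, -1)
  p <- ncol(x)
  obj <- function(par) {
    w <- par[1:p]; b <- par[p + 1]
    m <- drop(x %*% w) + b
    s <- pmax(0, 1 - y * m)
    0.5 * sum(w^2) + C * sum(s^2)
  }
  grad <- function(par) {
    w <- par[1:p]; b <- par[p + 1]
    m <- drop(x %*% w) + b
    s <- pmax(0, 1 - y * m)
    gw <- w - 2 * C * drop(crossprod(x, s * y))
    gb <- -2 * C * sum(s * y)
    c(gw, gb)
  }
  res <- stats::optim(rep(0, p + 1), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 500))
  list(w = res$par[1:p], b = res$par[p + 1])
}

# ---- random forest (bagged Gini CART) ----------------------------------
# Hand-rolled because no tree package is available here: bootstrap
# aggregation of depth-limited CART trees, mtry features per split,
# probability = mean terminal class-1 fraction across trees.
rf_fit <- function(x, y01, n_trees = 100L, min_node = 2L, max_depth = 8L,
                   seed = 1L) {
  set.seed(seed)
  n <- nrow(x); p <- ncol(x)
  mtry <- max(1L, floor(sqrt(p)))
  importance <- numeric(p)
  gini <- function(y) { pr <- mean(y); 2 * pr * (1 - pr) }
  build <- function(rows, depth) {
    yr <- y01[rows]
    if (depth >= max_depth || length(rows) < min_node ||
        length(unique(yr)) == 1L)
      return(list(leaf = TRUE, prob = mean(yr)))
    feats <- sample.int(p, mtry)
    best <- NULL; best_dec <- 0
    imp_parent <- gini(yr) * length(rows)
    for (f in feats) {
      v <- x[rows, f]
      o <- order(v)
      vs <- v[o]; ys <- yr[o]
      distinct <- which(diff(vs) > 0)
      if (!length(distinct)) next
      cs <- cumsum(ys)
      nl <- distinct
      n1l <- cs[distinct]
      nr <- length(rows) - nl
      n1r <- sum(yr) - n1l
      gl <- 2 * (n1l / nl) * (1 - n1l / nl) * nl
      gr <- 2 * (n1r / nr) * (1 - n1r / nr) * nr
      dec <- imp_parent - gl - gr
      ib <- which.max(dec)
      if (dec[ib] > best_dec + 1e-12) {
        best_dec <- dec[ib]
        best <- list(feature = f,
                     threshold = (vs[distinct[ib]] +
                                    vs[distinct[ib] + 1L]) / 2)
      }
    }
    if (is.null(best)) return(list(leaf = TRUE, prob = mean(yr)))
    importance[best$feature] <<- importance[best$feature] + best_dec
    left <- rows[x[rows, best$feature] <= best$threshold]
    right <- setdiff(rows, left)
    list(leaf = FALSE, feature = best$feature,
         threshold = best$threshold,
         left = build(left, depth + 1L),
         right = build(right, depth + 1L))
  }
  trees <- lapply(seq_len(n_trees), function(t) {
    rows <- sample.int(n, n, replace = TRUE)
    build(rows, 0L)
  })
  list(trees = trees, importance = importance / n_trees)
}

rf_predict_one <- function(node, xrow) {
  while (!node$leaf)
    node <- if (xrow[node$feature] <= node$threshold) node$left else
      node$right
  node$prob
}

rf_predict <- function(trees, x) {
  apply(x, 1, function(r)
    mean(vapply(trees, rf_predict_one, numeric(1), xrow = r)))
}

# ------------------------------------------------------------------------

#' Out-of-fold progression scores under stratified cross-validation
#'
#' Splits the Control+PD subjects into `k` stratified folds, trains one
#' model per fold on the remaining subjects, and scores each subject with
#' the single model whose test fold contains it.  The k fold models are
#' retained as a `model_ensemble` for model-averaged scoring of an
#' independent cohort.
#'
#' @param features Numeric matrix (subjects x 360), rownames = subject
#'   ids.
#' @param labels Binary group labels aligned with `features` rows.
#' @param spec A [model_spec()].
#' @param k Number of folds; the study design uses the size of the
#'   positive class (21).
#' @param seed Integer seed (drives the fold split and any stochastic
#'   family).
#' @return List with `scores` (data frame: subject_id, label, score,
#'   fold, provenance = "out_of_fold") and `ensemble`
#'   (`model_ensemble`: fold models, fold assignment, k, spec).
#' @export
cross_validated_scores <- function(features, labels, spec, k, seed) {
  stopifnot(is.matrix(features))
  y <- as_binary(labels)
  fold <- stratified_folds(labels, k, seed)
  n <- nrow(features)
  score <- numeric(n)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    m <- train_fold(features[train, , drop = FALSE], y[train], spec,
                    seed = seed + f)
    models[[f]] <- m
    if (length(test))
      score[test] <- predict(m, features[test, , drop = FALSE])
  }
  ids <- rownames(features)
  if (is.null(ids)) ids <- sprintf("subj%03d", seq_len(n))
  scores <- data.frame(subject_id = ids,
                       label = as.character(labels),
                       score = score, fold = fold,
                       provenance = "out_of_fold",
                       stringsAsFactors = FALSE)
  ensemble <- structure(list(fold_models = models, fold_assignment = fold,
                             k = k, spec = spec, seed = seed),
                        class = "model_ensemble")
  list(scores = scores, ensemble = ensemble)
}

#' Model-averaged scores for an independent cohort
#'
#' Scores subjects never seen in training by averaging the predicted
#' probabilities of all k fold models (unweighted arithmetic mean).  This
#' yields a single progression score per independent subject while using
#' every fold model symmetrically.
#'
#' @param ensemble A `model_ensemble` from [cross_validated_scores()].
#' @param features Feature matrix of the independent cohort.
#' @return Data frame: subject_id, score, provenance =
#'   "model_averaged".
#' @export
ensemble_predict <- function(ensemble, features) {
  stopifnot(inherits(ensemble, "model_ensemble"), is.matrix(features))
  preds <- vapply(ensemble$fold_models, predict, numeric(nrow(features)),
                  newdata = features)
  if (nrow(features) == 1L) preds <- matrix(preds, nrow = 1)
  ids <- rownames(features)
  if (is.null(ids)) ids <- sprintf("subj%03d", seq_len(nrow(features)))
  data.frame(subject_id = ids, score = unname(rowMeans(preds)),
             provenance = "model_averaged", stringsAsFactors = FALSE)
}
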