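test_that("auc equals the Mann-Whitney pair count", {
  expect_equal(auc(c(0.2, 0.6, 0.4, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3)), 1)
  expect_equal(auc(rep(0.5, 6), rep(c(0, 1), each = 3)), 0.5)
  expect_error(auc(1:4, rep(1, 4)), "both classes")

  # oracle equivalence on random instances, including heavy ties
  set.seed(101)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- if (i %% 2) runif(n) else sample(seq(0, 1, 0.25), n,
                                          replace = TRUE)
    expect_equal(auc(s, y), brute_auc(s, y), tolerance = 1e-12)
  }
})

test_that("roc_curve spans (0,0) to (1,1) and integrates to the AUC", {
  r <- roc_curve(c(0.1, 0.9), c(0, 1))
  expect_true(any(r$fpr == 0 & r$tpr == 1))  # the perfect corner
  set.seed(55)
  for (i in 1:100) {
    n <- sample(4:25, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- if (i %% 3) runif(n) else sample(seq(0, 1, 0.2), n,
                                          replace = TRUE)
    rc <- roc_curve(s, y)
    expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
    expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
    expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
    expect_equal(trapezoid_auc(rc), auc(s, y), tolerance = 1e-12)
  }
})

test_that("optimal_threshold maximizes sens^2 + spec^2", {
  # spec example: pos = {0.9, 0.8, 0.4}, neg = {0.3, 0.2, 0.6}
  s <- c(0.9, 0.8, 0.4, 0.3, 0.2, 0.6)
  y <- c(1, 1, 1, 0, 0, 0)
  expect_equal(optimal_threshold(roc_curve(s, y)), scan_threshold(s, y))

  # perfectly separated scores: midpoint of the separating gap
  sp <- c(0.1, 0.2, 0.7, 0.9); yp <- c(0, 0, 1, 1)
  thr <- optimal_threshold(roc_curve(sp, yp))
  expect_equal(thr, 0.45)
  cm <- classification_metrics(sp, yp, thr)
  expect_equal(cm$sensitivity, 1); expect_equal(cm$specificity, 1)

  # exhaustive-scan oracle on random instances; the returned threshold
  # always attains the maximum of the criterion
  set.seed(77)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 2)
    rc <- roc_curve(s, y)
    thr <- optimal_threshold(rc)
    expect_equal(thr, scan_threshold(s, y))
    # thr can fall just outside [0, 1] when classifying everything
    # positive is optimal; the range warning is expected there
    cm <- suppressWarnings(classification_metrics(s, y, thr))
    expect_equal(cm$sensitivity^2 + cm$specificity^2,
                 max(rc$sensitivity^2 + rc$specificity^2),
                 tolerance = 1e-12)
  }
})

test_that("classification metrics match hand computation", {
  # confusion table TP=19, FN=2, TN=23, FP=7
  s <- c(rep(0.9, 19), rep(0.1, 2), rep(0.1, 23), rep(0.9, 7))
  y <- rep(c(1, 0), c(21, 30))
  m <- classification_metrics(s, y, 0.5)
  expect_equal(m$confusion, c(tp = 19L, fn = 2L, tn = 23L, fp = 7L))
  sens <- 19 / 21; spec <- 23 / 30
  expect_equal(m$sensitivity, sens)
  expect_equal(m$specificity, spec)
  expect_equal(m$balanced_accuracy, (sens + spec) / 2)
  po <- 42 / 51
  pe <- (26 * 21 + 25 * 30) / 51^2
  expect_equal(m$kappa, (po - pe) / (1 - pe))

  # perfect classifier
  mp <- classification_metrics(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(unlist(mp[c("sensitivity", "specificity",
                           "balanced_accuracy", "kappa")]),
               c(sensitivity = 1, specificity = 1,
                 balanced_accuracy = 1, kappa = 1))

  # label-independent predictions at prevalence: kappa near zero
  set.seed(8)
  y2 <- rep(c(0, 1), each = 250)
  s2 <- runif(500)
  m2 <- classification_metrics(s2, y2, 0.5)
  expect_lt(abs(m2$kappa), 0.12)

  expect_warning(classification_metrics(s2, y2, 1.5), "outside")
})

test_that("bootstrap CI is self-consistent and degenerates correctly", {
  # perfect separation: every resample keeps AUC 1
  s <- c(rep(0.9, 10), rep(0.1, 10)); y <- rep(c(1, 0), each = 10)
  bs <- bootstrap_ci(s, y, n_reps = 200, seed = 3)
  expect_equal(bs$ci_low, 1); expect_equal(bs$ci_high, 1)

  set.seed(42)
  s2 <- c(rnorm(20, 1), rnorm(25)); y2 <- rep(c(1, 0), c(20, 25))
  bs2 <- bootstrap_ci(s2, y2, n_reps = 500, seed = 9)
  expect_length(bs2$replicates, 500L)
  # reported percentiles equal direct quantiles of the stored replicates
  expect_equal(bs2$ci_low,
               unname(stats::quantile(bs2$replicates, 0.05)))
  expect_equal(bs2$ci_high,
               unname(stats::quantile(bs2$replicates, 0.95)))
  expect_true(all(bs2$roc_band$tpr_high >= bs2$roc_band$tpr_low))

  expect_warning(bootstrap_ci(c(1, 0, 1, 0.5), c(1, 0, 1, 0),
                              n_reps = 50, seed = 1), "fewer than 4")
})

test_that("bootstrap CI width shrinks with sample size", {
  widths <- vapply(c(40, 160), function(n) {
    set.seed(500 + n)
    s <- c(rnorm(n / 2, 1.2), rnorm(n / 2))
    y <- rep(c(1, 0), each = n / 2)
    bs <- bootstrap_ci(s, y, n_reps = 400, seed = 11)
    bs$ci_high - bs$ci_low
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("covariate-adjusted p behaves under signal, null and separation", {
  set.seed(19)
  n <- 51
  age <- rnorm(n, 66, 5); gender <- sample(c("M", "F"), n, TRUE)
  y <- rep(c(0, 1), c(30, 21))

  # strongly predictive score
  s_good <- y * 0.7 + runif(n) * 0.3
  r <- covariate_adjusted_p(s_good, y, age, gender)
  expect_lt(r$p, 0.05)
  expect_gt(r$coef, 0)

  # perfectly separating score triggers the penalized fallback
  s_sep <- ifelse(y == 1, 0.9, 0.1)
  rs <- covariate_adjusted_p(s_sep, y, age, gender)
  expect_identical(rs$method, "firth")
  expect_true(is.finite(rs$p) && rs$p >= 0 && rs$p <= 1)
  expect_lt(rs$p, 0.05)

  expect_error(covariate_adjusted_p(rep(0.5, n), y, age, gender),
               "constant")
})

test_that("scalar markers are auto-oriented and evaluated", {
  y <- rep(c(0, 1), each = 15)
  r <- scalar_marker_eval(as.numeric(y), y)
  expect_equal(r$auc, 1)
  expect_false(r$flipped)

  # reversed orientation (cognitive-style scale) gets flipped
  set.seed(4)
  v <- 30 - 5 * y + rnorm(30)
  rf <- scalar_marker_eval(v, y)
  expect_true(rf$flipped)
  expect_gt(rf$auc, 0.9)

  rnd <- scalar_marker_eval(rnorm(200), rep(c(0, 1), 100))
  expect_gte(rnd$auc, 0.5)   # flip keeps it above chance by construction
  expect_lt(rnd$auc, 0.65)

  expect_error(scalar_marker_eval(rep(3, 30), y), "constant")
})

test_that("synthetic clinical scales mirror cross-sectional vs longitudinal contrast", {
  cfg <- simulation_config(seed = 23L)
  coh <- simulate_cohort(cfg)
  cl <- simulate_clinical(cfg, coh)
  man <- coh$manifest
  base <- cl[cl$visit == 0, ]
  y1 <- cl[cl$visit == 1, ]
  cp <- man$group %in% c("CNT", "PD")
  lab <- man$group[cp]

  # cross-sectional UPDRS-III separates PD from Controls almost perfectly
  b_cp <- base[match(man$subject_id[cp], base$subject_id), ]
  cs <- scalar_marker_eval(b_cp$updrs3, lab)
  expect_gt(cs$auc, 0.9)

  # its one-year change on the prodromal-vs-control contrast is weaker
  pr <- man$group %in% c("CNT", "PROD")
  d_updrs <- y1$updrs3[match(man$subject_id[pr], y1$subject_id)] -
    base$updrs3[match(man$subject_id[pr], base$subject_id)]
  ls <- scalar_marker_eval(d_updrs, ifelse(man$group[pr] == "PROD", 1, 0))
  expect_lt(ls$auc, cs$auc)
})

test_that("evaluate_scores bundles a coherent report", {
  set.seed(71)
  y <- rep(c(0, 1), c(30, 21))
  s <- plogis(rnorm(51, mean = y * 2))
  age <- rnorm(51, 66, 5); gender <- sample(c("M", "F"), 51, TRUE)
  rep_ <- evaluate_scores(s, y, age, gender, n_boot = 200, seed = 2)
  expect_s3_class(rep_, "evaluation_report")
  expect_equal(rep_$auc, auc(s, y))
  expect_equal(rep_$n_pos, 21L); expect_equal(rep_$n_neg, 30L)
  expect_equal(rep_$chosen_threshold,
               optimal_threshold(rep_$roc))
  expect_equal(rep_$metrics_optimal$balanced_accuracy,
               (rep_$metrics_optimal$sensitivity +
                  rep_$metrics_optimal$specificity) / 2)
  expect_true(rep_$metrics_05$kappa >= -1 && rep_$metrics_05$kappa <= 1)
  expect_true(is.finite(rep_$adjusted_p))
})
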