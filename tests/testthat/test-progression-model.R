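test_that("stratified folds partition subjects and preserve class balance", {
  labels <- rep(c("CNT", "PD"), c(30, 21))
  fold <- stratified_folds(labels, k = 21, seed = 4)
  expect_length(fold, 51L)
  expect_setequal(unique(fold), 1:21)
  sizes <- tabulate(fold, 21)
  expect_true(all(sizes %in% c(2L, 3L)))          # 2 or 3 subjects per fold
  per_class <- table(fold, labels)
  expect_true(all(per_class[, "PD"] == 1L))       # 21 PD over 21 folds
  expect_true(all(per_class[, "CNT"] %in% c(1L, 2L)))

  # leave-one-out when k = n
  loo <- stratified_folds(rep(c(0, 1), 5), k = 10, seed = 1)
  expect_setequal(loo, 1:10)

  # determinism given seed
  expect_identical(stratified_folds(labels, 21, seed = 9),
                   stratified_folds(labels, 21, seed = 9))

  expect_error(stratified_folds(labels, k = 52, seed = 1), "k <= n")
  expect_error(stratified_folds(rep("A", 10), k = 2, seed = 1),
               "two classes|single-class")
})

test_that("train_fold fits each family and respects its contracts", {
  # linearly separable toy set: training accuracy 1 for every family
  set.seed(21)
  x <- cbind(c(rnorm(4, -3), rnorm(4, 3)), rnorm(8))
  y <- rep(c(0, 1), each = 4)
  for (fam in c("logreg_l1", "logreg_l2", "elastic_net", "linear_svm",
                "random_forest")) {
    m <- train_fold(x, y, model_spec(fam), seed = 2)
    acc <- mean((predict(m, x) >= 0.5) == y)
    expect_equal(acc, 1, info = fam)
    expect_true(all(predict(m, x) >= 0 & predict(m, x) <= 1))
  }

  # uninformative (all-zero) features: L1 drops every weight and the
  # intercept reproduces the class prior
  xz <- matrix(0, 12, 2)
  yz <- rep(c(0, 1), c(8, 4))
  mz <- train_fold(xz, yz, model_spec("logreg_l1"))
  expect_true(all(mz$weights == 0))
  expect_equal(unique(predict(mz, xz)), 1 / 3, tolerance = 1e-6)

  expect_error(train_fold(x, rep(0, 8), model_spec("logreg_l1")),
               "single-class")
  xbad <- x; xbad[1, 1] <- NA
  expect_error(train_fold(xbad, y, model_spec("logreg_l1")),
               "non-finite")
})

test_that("L1 fit on the synthetic cohort is sparse", {
  coh <- simulate_cohort(simulation_config(seed = 13L))
  man <- coh$manifest
  tr <- man$group %in% c("CNT", "PD")
  m <- train_fold(coh$features[tr, ], man$group[tr],
                  model_spec("logreg_l1"))
  expect_length(m$weights, 360L)
  expect_gte(mean(m$weights == 0), 0.5)
})

test_that("out-of-fold scores come from the holding fold's model only", {
  cfg <- tiny_config(seed = 3L)
  coh <- simulate_cohort(cfg)
  man <- coh$manifest
  tr <- man$group %in% c("CNT", "PD")
  x <- coh$features[tr, ]; y <- man$group[tr]
  cv <- cross_validated_scores(x, y, model_spec("logreg_l1"), k = 4,
                               seed = 8)
  expect_true(all(cv$scores$score >= 0 & cv$scores$score <= 1))
  expect_equal(cv$scores$provenance, rep("out_of_fold", nrow(x)))
  expect_length(cv$ensemble$fold_models, 4L)
  # recompute each subject's score from its fold model
  for (s in seq_len(nrow(x))) {
    f <- cv$scores$fold[s]
    expect_equal(cv$scores$score[s],
                 unname(predict(cv$ensemble$fold_models[[f]],
                                x[s, , drop = FALSE])))
  }
})

test_that("ensemble prediction averages fold-model probabilities", {
  cfg <- tiny_config(seed = 6L)
  coh <- simulate_cohort(cfg)
  man <- coh$manifest
  tr <- man$group %in% c("CNT", "PD")
  cv <- cross_validated_scores(coh$features[tr, ], man$group[tr],
                               model_spec("logreg_l1"), k = 4, seed = 2)
  xp <- coh$features[man$group == "PROD", ]
  pred <- ensemble_predict(cv$ensemble, xp)
  per_model <- vapply(cv$ensemble$fold_models, predict,
                      numeric(nrow(xp)), newdata = xp)
  expect_equal(pred$score, unname(rowMeans(per_model)))
  expect_true(all(pred$score >= apply(per_model, 1, min) - 1e-12))
  expect_true(all(pred$score <= apply(per_model, 1, max) + 1e-12))

  # identical models -> averaged score equals the single-model score
  ens1 <- cv$ensemble
  ens1$fold_models <- rep(ens1$fold_models[1], 4)
  p1 <- ensemble_predict(ens1, xp)
  expect_equal(p1$score,
               unname(predict(ens1$fold_models[[1]], xp)))

  # permuting the independent rows permutes the scores identically
  perm <- sample(nrow(xp))
  expect_equal(ensemble_predict(cv$ensemble, xp[perm, ])$score,
               pred$score[perm])

  expect_error(ensemble_predict(cv$ensemble, xp[, 1:10]),
               "dimension mismatch")
})

test_that("independent cohort never influences the fold models", {
  cfg <- tiny_config(seed = 14L)
  coh <- simulate_cohort(cfg)
  man <- coh$manifest
  tr <- man$group %in% c("CNT", "PD")
  x <- coh$features[tr, ]; y <- man$group[tr]
  cv1 <- cross_validated_scores(x, y, model_spec("logreg_l1"), k = 4,
                                seed = 5)
  # refit after perturbing PROD features (they are simply not passed in,
  # so equality here checks determinism; the firewall is structural)
  cv2 <- cross_validated_scores(x, y, model_spec("logreg_l1"), k = 4,
                                seed = 5)
  expect_identical(cv1$scores, cv2$scores)
  expect_identical(lapply(cv1$ensemble$fold_models, `[[`, "weights"),
                   lapply(cv2$ensemble$fold_models, `[[`, "weights"))
})

test_that("random forest is seed-deterministic and finds an easy signal", {
  set.seed(99)
  x <- cbind(sig = rep(c(0, 3), each = 10) + rnorm(20, 0, 0.3),
             matrix(rnorm(20 * 5), 20, 5))
  y <- rep(c(0, 1), each = 10)
  m1 <- train_fold(x, y, model_spec("random_forest"), seed = 7)
  m2 <- train_fold(x, y, model_spec("random_forest"), seed = 7)
  expect_identical(predict(m1, x), predict(m2, x))
  expect_null(m1$weights)
  expect_equal(which.max(m1$importance), 1L)   # the informative column
})

test_that("sparse implanted effects favour the L1 model over L2 and SVM", {
  reps <- 3
  aucs <- matrix(NA_real_, reps, 3,
                 dimnames = list(NULL, c("logreg_l1", "logreg_l2",
                                         "linear_svm")))
  for (r in seq_len(reps)) {
    coh <- simulate_cohort(simulation_config(n_cnt = 20, n_pd = 14,
                                             n_prod = 2,
                                             seed = 300L + r))
    man <- coh$manifest
    tr <- man$group %in% c("CNT", "PD")
    for (fam in colnames(aucs)) {
      cv <- cross_validated_scores(coh$features[tr, ], man$group[tr],
                                   model_spec(fam), k = 7,
                                   seed = 300L + r)
      aucs[r, fam] <- auc(cv$scores$score, man$group[tr])
    }
  }
  m <- colMeans(aucs)
  expect_gte(m["logreg_l1"], m["logreg_l2"])
  expect_gte(m["logreg_l1"], m["linear_svm"])
})
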