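test_that("correlation stage keeps one of each duplicated pair", {
  tc <- tabular_cohort(100, 4, informative = 1, seed = 2)
  X <- tc$X
  X$dup <- X$f1  # r = 1 with f1
  sel <- reduce_features(X, tc$y, "corr+lasso", seed = 1)
  expect_false(all(c("f1", "dup") %in% sel))
})

test_that("chains are monotone and an exhausted chain warns and returns empty", {
  tc <- tabular_cohort(120, 8, informative = c(1, 2), seed = 3)
  for (ch in omr_chain_names) {
    sel <- suppressWarnings(reduce_features(tc$X, tc$y, ch, seed = 4))
    expect_true(all(sel %in% colnames(tc$X)), label = ch)
  }
  # pure noise, tiny signal: univariate stage may legitimately empty the set
  null <- tabular_cohort(60, 5, seed = 11)
  expect_warning(
    out <- reduce_features(null$X, rep(c(0, 1), 30), "lr+lasso", seed = 1),
    "empty")
  expect_length(out, 0)
  expect_error(reduce_features(tc$X, rep(1, 120), "lasso+stepwise"), "single class")
})

test_that("importance rankers cap the candidate set at min(20, p)", {
  tc <- tabular_cohort(150, 30, informative = c(1, 2, 3), beta = 1.2, seed = 5)
  for (st in c("rf", "xgboost", "gbm", "svm")) {
    kept <- omrad:::with_local_seed(1,
      omrad:::stage_ranker(tc$X, tc$y, colnames(tc$X), st))
    expect_length(kept, 20)
  }
})

test_that("planted 3-of-50 support is recovered by lasso+stepwise across seeds", {
  hits <- 0
  for (sd in 1:5) {
    tc <- tabular_cohort(400, 50, informative = 1:3, beta = 1, seed = 300 + sd)
    sel <- suppressWarnings(
      reduce_features(tc$X, tc$y, "lasso+stepwise", seed = sd))
    if (all(c("f1", "f2", "f3") %in% sel)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("logistic signature recovers known coefficients and is deterministic", {
  set.seed(9)
  n <- 5000
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(-1 + 0.8 * X$a - 0.5 * X$b))
  sig <- fit_logistic_signature(X, y, c("a", "b"))
  beta_raw <- sig$coef / sig$scale
  expect_equal(unname(beta_raw), c(0.8, -0.5), tolerance = 0.1)
  expect_equal(sig$intercept - sum(sig$coef * sig$center / sig$scale), -1,
               tolerance = 0.1)
  s1 <- predict(sig, X)
  expect_identical(s1, predict(sig, X))

  # perfect separation: scores rank all positives above all negatives
  Xs <- data.frame(z = c(rnorm(20, -3), rnorm(20, 3)))
  ys <- rep(c(0, 1), each = 20)
  sig2 <- suppressMessages(fit_logistic_signature(Xs, ys, "z"))
  expect_equal(roc_auc_ci(predict(sig2, Xs), ys)$auc, 1)
  expect_error(fit_logistic_signature(X, y, character(0)), "empty feature")
})

test_that("cross-validated AUC partitions samples, is deterministic, and is ~0.5 under the null", {
  tc <- tabular_cohort(300, 8, seed = 6)
  y <- omrad:::with_local_seed(8, sample(rep(0:1, 150)))  # labels independent of X
  cv1 <- suppressWarnings(crossval_auc(tc$X, y, "lasso+stepwise", seed = 7))
  cv2 <- suppressWarnings(crossval_auc(tc$X, y, "lasso+stepwise", seed = 7))
  expect_identical(cv1$fold_auc, cv2$fold_auc)
  expect_equal(sort(unique(cv1$foldid)), 1:10)
  expect_equal(as.vector(table(cv1$foldid)), rep(30, 10))  # each sample in one fold
  expect_lt(abs(cv1$mean_auc - 0.5), 0.07)
  expect_error(crossval_auc(tc$X[1:12, ], y[1:12], "lasso+stepwise", folds = 10),
               "folding error")
})

test_that("no information leaks from validation folds into selection", {
  # a feature informative ONLY on the validation rows of fold 1 must not
  # raise the cross-validated AUC: selection is re-run inside each fold
  tc <- tabular_cohort(200, 6, seed = 14)
  y <- omrad:::with_local_seed(15, sample(rep(0:1, 100)))
  base <- suppressWarnings(crossval_auc(tc$X, y, "corr+lasso", seed = 16))
  X2 <- tc$X
  X2$leak <- rnorm(200, sd = 0.1)
  val1 <- base$foldid == 1                    # same folds: derived from seed
  X2$leak[val1] <- ifelse(y[val1] == 1, 5, -5)
  cv <- suppressWarnings(crossval_auc(X2, y, "corr+lasso", seed = 16))
  expect_identical(cv$foldid, base$foldid)
  expect_lt(cv$fold_auc[1], 0.75)
  expect_lt(abs(cv$mean_auc - 0.5), 0.1)
})
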