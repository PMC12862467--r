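search_fixture <- function(seed = 1, n = 150, p = 5, max_mm = 2) {
  tabular_features_by_spec(n, p, enumerate_band_specs(max_mm), seed = seed)
}

test_that("every (spec, chain) pair yields one ranked record", {
  fs <- search_fixture(seed = 2)
  s <- suppressWarnings(omr_search(fs, chains = c("lasso+stepwise", "corr+lasso"),
                                   seed = 3))
  expect_equal(nrow(s$results), length(fs) * 2)
  expect_equal(s$results$rank, seq_len(nrow(s$results)))
  expect_true(all(s$results$auc_internal <= 1 & s$results$auc_internal >= 0,
                  na.rm = TRUE))
  expect_true(all(s$results$auc_internal_lo <= s$results$auc_internal,
                  na.rm = TRUE))
})

test_that("the ranking does not depend on evaluation order", {
  fs <- search_fixture(seed = 4)
  s1 <- suppressWarnings(omr_search(fs, chains = "corr+lasso", seed = 5))
  s2 <- suppressWarnings(omr_search(rev(fs), chains = "corr+lasso", seed = 5))
  expect_equal(s1$results[, c("spec", "chain", "auc_internal")],
               s2$results[, c("spec", "chain", "auc_internal")])
})

test_that("ties in internal AUC resolve to the narrower band", {
  specs <- enumerate_band_specs(2)
  fs <- tabular_features_by_spec(80, 3, specs, seed = 6)
  # identical feature tables for every spec force exact AUC ties
  for (nm in names(fs)) fs[[nm]][, 4:6] <- fs[[1]][, 4:6]
  s <- suppressWarnings(omr_search(fs, chains = "corr+lasso", seed = 7))
  res <- s$results
  widths <- ifelse(res$is_original, Inf, res$inner_mm + res$outer_mm)
  expect_true(all(diff(widths) >= 0))
  expect_false(res$is_original[1])  # original counts as the widest region
})

test_that("selection optimism: the max internal AUC over a null grid beats chance while external stays honest", {
  fs <- tabular_features_by_spec(400, 6, enumerate_band_specs(3), seed = 8,
                                 cohorts = c(0.5, 0.25, 0.25), signal = 0)
  s <- suppressWarnings(omr_search(fs, chains = c("corr+lasso", "lasso+stepwise"),
                                   seed = 9))
  best <- s$results[1, ]
  expect_gt(best$auc_internal, 0.55)   # winner's curse across many models
  expect_lt(abs(best$auc_external - 0.5), 0.15)
})

test_that("patients with empty bands are dropped per spec; sparse specs are skipped", {
  fs <- search_fixture(seed = 10, n = 60)
  fs[[2]][1:5, 4:8] <- NA           # five patients missing for one spec
  fs[[3]][1:40, 4:8] <- NA          # two thirds missing: spec skipped
  expect_warning(s <- omr_search(fs, chains = "corr+lasso", seed = 11),
                 "skipped")
  expect_false(names(fs)[3] %in% s$results$spec)
  r2 <- s$results[s$results$spec == names(fs)[2], ]
  expect_lt(r2$n_train + r2$n_internal + r2$n_external, 60)
})

test_that("summarize_top_regions slices the ranking deterministically", {
  fs <- search_fixture(seed = 12)
  s <- suppressWarnings(omr_search(fs, chains = "corr+lasso", seed = 13))
  top1 <- summarize_top_regions(s, 1)
  expect_equal(nrow(top1), 1)
  expect_equal(top1$auc_internal, max(s$results$auc_internal, na.rm = TRUE))
  expect_equal(nrow(summarize_top_regions(s, 10000)), nrow(s$results))
  expect_error(summarize_top_regions(s, 0), "parameter error")
})

test_that("the top model scores new data deterministically and supports groups", {
  fs <- search_fixture(seed = 14)
  s <- suppressWarnings(omr_search(fs, chains = "lasso+stepwise", seed = 15))
  m <- s$top
  expect_s3_class(m, "omr_model")
  newX <- fs[[s$results$spec[1]]]
  sc <- predict(m, newX)
  expect_identical(sc, predict(m, newX))
  expect_error(predict(m, newX, type = "group"), "cutoff")
  m$cutoff <- median(sc)
  g <- predict(m, newX, type = "group")
  expect_true(all(levels(g) == c("low", "high")))
})
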