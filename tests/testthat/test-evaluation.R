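test_that("AUC examples and rank invariance", {
  expect_equal(roc_auc_ci(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc_ci(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  set.seed(31)
  s <- rnorm(60); y <- rbinom(60, 1, 0.5); y[1:2] <- 0:1
  a1 <- roc_auc_ci(s, y)$auc
  expect_equal(roc_auc_ci(exp(s), y)$auc, a1)        # monotone transform
  expect_equal(roc_auc_ci(rank(s), y)$auc, a1)
  expect_error(roc_auc_ci(s, rep(1, 60)), "single class")
})

test_that("AUC and its DeLong interval match brute force and pROC on random fixtures", {
  skip_if_not_installed("pROC")
  for (f in 1:20) {
    set.seed(400 + f)
    n <- sample(20:60, 1)
    s <- round(rnorm(n), 1)  # rounding forces ties
    y <- rbinom(n, 1, 0.5); y[1:2] <- 0:1
    got <- roc_auc_ci(s, y)
    expect_lt(abs(got$auc - oracle_auc(s, y)), 1e-12)
    pr <- pROC::ci.auc(pROC::roc(y, s, quiet = TRUE, direction = "<"),
                       method = "delong")
    expect_equal(got$auc, as.numeric(pr[2]), tolerance = 1e-12)
    expect_equal(got$ci, pmin(pmax(as.numeric(pr[c(1, 3)]), 0), 1),
                 tolerance = 1e-9)
  }
})

test_that("Youden cutoff equals exhaustive search and handles degenerate scores", {
  for (f in 1:50) {
    set.seed(500 + f)
    n <- sample(10:40, 1)
    s <- round(rnorm(n), 1)
    y <- rbinom(n, 1, 0.5); y[1:2] <- 0:1
    got <- youden_cutoff(s, y)
    want <- oracle_youden(s, y)
    expect_equal(got$J, want$J, tolerance = 1e-12)
    expect_equal(got$cutoff, want$cutoff, tolerance = 1e-12)
  }
  sep <- youden_cutoff(c(1, 2, 8, 9), c(0, 0, 1, 1))
  expect_equal(sep$J, 1)
  expect_equal(sep$cutoff, 5)
  flat <- youden_cutoff(rep(2, 10), rep(c(0, 1), 5))
  expect_equal(flat$J, 0)
})

test_that("KM reduces to the empirical survivor function without censoring", {
  set.seed(61)
  t1 <- rexp(40, 0.05); t2 <- rexp(40, 0.15)
  km <- km_logrank(rep(c("low", "high"), each = 40), c(t1, t2), rep(1, 80))
  med <- km$medians
  expect_equal(med$median[med$group == "low"], median(t1), tolerance = 1e-8)
  expect_equal(med$median[med$group == "high"], median(t2), tolerance = 1e-8)
  # the product-limit estimate equals 1 - ECDF at every event time
  sf <- summary(km$fit)
  grp2 <- sf$strata == "group=low"
  emp <- 1 - stats::ecdf(t1)(sf$time[grp2])
  expect_equal(sf$surv[grp2], emp, tolerance = 1e-12)
})

test_that("log-rank is zero on identical groups and matches the hand-worked toy", {
  tm <- c(5, 8, 12, 5, 8, 12)
  ev <- rep(1, 6)
  g <- rep(c("low", "high"), each = 3)
  km <- km_logrank(g, tm, ev)
  expect_equal(km$chisq, 0, tolerance = 1e-12)
  expect_equal(km$p, 1, tolerance = 1e-12)

  # A = {1,2,3}, B = {4,5,6}, all events: O-E over the six risk sets for
  # group A is (1-1/2)+(1-2/5... worked by direct risk-set table:
  # risk sets at t=1..6 have sizes 6,5,4,3,2,1; group A at risk 3,2,1,0,0,0
  # expected A events: 3/6+2/5+1/4 = 1.15; observed 3; V = sum of
  # hypergeometric variances = 0.25+0.24+0.1875 = 0.6775... wait d=1 each:
  # V_t = nA*nB*d*(n-d)/(n^2*(n-1)) = (3*3*1*5)/(36*5), (2*3*4... compute:
  vA <- c(3 * 3 * 1 * 5 / (36 * 5), 2 * 3 * 1 * 4 / (25 * 4),
          1 * 3 * 1 * 3 / (16 * 3))
  OmE <- 3 - (3 / 6 + 2 / 5 + 1 / 4)
  want <- OmE^2 / sum(vA)
  km2 <- km_logrank(rep(c("A", "B"), each = 3), c(1, 2, 3, 4, 5, 6), rep(1, 6))
  expect_equal(km2$chisq, want, tolerance = 1e-10)
  expect_error(km_logrank(rep("A", 6), c(1, 2, 3, 4, 5, 6), rep(1, 6)),
               "input error")
})

test_that("association test choice follows the expected-count rule", {
  # 2x2, all expected >= 5: Yates-corrected chi-square
  r <- association_table(rbind(c(20, 10), c(12, 18)))
  expect_equal(r$test, "chi-square-yates")
  # r x c with all expected >= 5: plain Pearson
  r2 <- association_table(rbind(c(20, 10), c(12, 18), c(15, 15)))
  expect_equal(r2$test, "chi-square")
  # small expected count: Fisher exact
  r3 <- association_table(rbind(c(2, 8), c(9, 1)))
  expect_equal(r3$test, "fisher")
  # no association: p formats as > .999
  r4 <- association_table(rbind(c(10, 10), c(10, 10)))
  expect_equal(unname(r4$statistic), 0)
  expect_equal(r4$p_formatted, ">.999")
  expect_error(association_table(rbind(c(0, 0), c(1, 2))), "empty margin")
})

test_that("stratification freezes the training cutoff across cohorts", {
  set.seed(71)
  sc <- list(training = c(rnorm(40, 0), rnorm(40, 2)),
             internal_test = c(rnorm(20, 0), rnorm(20, 2)))
  lb <- list(training = rep(0:1, each = 40), internal_test = rep(0:1, each = 20))
  sv <- list(training = data.frame(time = rexp(80, 0.02) + 1, event = rbinom(80, 1, 0.8)),
             internal_test = data.frame(time = rexp(40, 0.02) + 1, event = rbinom(40, 1, 0.8)))
  st <- stratify_cohorts(sc, lb, sv)
  yc <- youden_cutoff(sc$training, lb$training)
  expect_equal(st$cutoff, yc$cutoff)
  expect_equal(as.character(st$groups$internal_test),
               ifelse(sc$internal_test > yc$cutoff, "high", "low"))
  expect_equal(sum(table(st$groups$training)), 80)
  expect_true(st$km$training$os$p >= 0 && st$km$training$os$p <= 1)
})
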