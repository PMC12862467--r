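small_params <- list(semi_axes = c(9, 11), margin_mm = 3)

test_that("the same seed reproduces a bit-identical cohort", {
  a <- generate_cohort(20, seed = 5, params = small_params)
  b <- generate_cohort(20, seed = 5, params = small_params)
  expect_identical(a$table, b$table)
  expect_identical(a$patients[[7]]$volume$voxels, b$patients[[7]]$volume$voxels)
  expect_identical(a$patients[[3]]$mask$voxels, b$patients[[3]]$mask$voxels)
  c2 <- generate_cohort(20, seed = 6, params = small_params)
  expect_false(identical(a$patients[[7]]$volume$voxels,
                         c2$patients[[7]]$volume$voxels))
})

test_that("phantom lesions match the analytic ellipsoid volume within 5%", {
  co <- generate_cohort(20, seed = 8, params = small_params)
  for (i in c(1, 5, 11)) {
    pt <- co$patients[[i]]
    vol_digital <- sum(pt$mask$voxels) * prod(pt$mask$spacing)
    vol_analytic <- 4 / 3 * pi * prod(pt$semi_axes)
    expect_lt(abs(vol_digital - vol_analytic) / vol_analytic, 0.05)
  }
})

test_that("the planted texture effect is measurable in the rim at effect 2", {
  co <- generate_cohort(100, seed = 9, params = list(semi_axes = c(9, 11),
                                                     margin_mm = 3,
                                                     effect_size = 2))
  rim_sd <- function(pt) {
    maps <- omrad:::band_distance_maps(pt$mask)
    rim <- omrad:::band_voxels_from_maps(maps, band_spec(5, 0))
    # deepest rim millimetre, where the planted variance gain peaks
    deep <- rim & maps$din2 >= 16
    sd(pt$volume$voxels[deep])
  }
  sds <- vapply(seq_len(100), function(i) rim_sd(co$patients[[i]]), 0)
  s1 <- sds[co$table$label == 1]
  s0 <- sds[co$table$label == 0]
  expect_gt(mean(s1), mean(s0))
  expect_lt(wilcox.test(s1, s0, alternative = "greater")$p.value, 0.01)
})

test_that("a null cohort (effect 1, hazard ratio 1) has uniform-ish log-rank p", {
  small <- 0
  for (sd in 1:20) {
    co <- generate_cohort(60, seed = 1000 + sd,
                          params = list(effect_size = 1, hazard_ratio = 1),
                          images = FALSE)
    tab <- co$table
    km <- km_logrank(factor(ifelse(tab$label == 1, "high", "low"),
                            levels = c("low", "high")),
                     tab$time, tab$event)
    if (km$p < 0.10) small <- small + 1
  }
  expect_lte(small, 5)  # ~2 of 20 expected; loose band
})

test_that("survival is label-coupled at the default hazard ratio", {
  co <- generate_cohort(400, seed = 21, images = FALSE)
  tab <- co$table
  km <- km_logrank(factor(ifelse(tab$label == 1, "high", "low"),
                          levels = c("low", "high")), tab$time, tab$event)
  expect_lt(km$p, 0.001)
})

test_that("truth_check reports rank and Manhattan distance", {
  res <- data.frame(spec = c("in4_out1", "in5_out0"), chain = "x",
                    inner_mm = c(4L, 5L), outer_mm = c(1L, 0L),
                    is_original = FALSE, rank = 1:2)
  fake <- structure(list(results = res), class = "omr_search")
  tc <- truth_check(fake, band_spec(5, 0))
  expect_equal(tc$distance, 2)
  expect_equal(tc$planted_rank, 2)
  expect_true(tc$recovered)
  res2 <- res[2:1, ]; res2$rank <- 1:2
  tc2 <- truth_check(structure(list(results = res2), class = "omr_search"),
                     band_spec(5, 0))
  expect_equal(tc2$distance, 0)
  expect_equal(tc2$planted_rank, 1)
})

test_that("cohort directories round-trip through patients.csv", {
  co <- generate_cohort(20, seed = 31, params = small_params)
  dir <- file.path(tempdir(), "phantom_cohort")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "patients.csv")))
  back <- read_cohort(dir)
  expect_equal(nrow(back$table), 20)
  expect_identical(back$patients[["P004"]]$volume$voxels,
                   co$patients[["P004"]]$volume$voxels)
  expect_equal(back$table$label, co$table$label)
  unlink(dir, recursive = TRUE)
  expect_error(read_cohort(tempdir()), "patients.csv")
})

test_that("generation guards its geometric preconditions", {
  expect_error(generate_cohort(10, seed = 1), ">= 20")
  expect_error(generate_cohort(20, seed = 1, params = list(semi_axes = c(5, 7))),
               "geometry error")
})

test_that("cavity phantoms drive the cohort nontarget report", {
  co <- generate_cohort(20, seed = 41,
                        params = list(semi_axes = c(9, 11), margin_mm = 5,
                                      cavity_fraction = 1))
  rep <- nontarget_cohort_report(co, list(band_spec(0, 5), band_spec(2, 0)))
  expect_true(all(c("patient_id", "inner_mm", "outer_mm", "label",
                    "voxels_outside") %in% names(rep)))
  outer5 <- rep[rep$outer_mm == 5, ]
  expect_gt(sum(outer5$voxels_outside, na.rm = TRUE), 0)   # cavity overlapped
  inner2 <- rep[rep$inner_mm == 2 & rep$outer_mm == 0, ]
  expect_true(all(inner2$voxels_outside == 0))             # inside the lesion
  # the cavity zeroes the image where it sits
  pt <- co$patients[[1]]
  expect_true(any(pt$volume$voxels == 0))
  expect_false(is.null(pt$organ))
})
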