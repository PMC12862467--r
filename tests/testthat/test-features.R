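test_that("discretization follows the min-anchored fixed-bin-width formula", {
  v <- volume_grid(array(c(0, 10, 25, 49, 100, 0, 0, 0), c(2, 2, 2)))
  m <- mask_volume(array(c(1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L), c(2, 2, 2)))
  r <- discretize(v, m, 25)
  expect_equal(r$levels, c(1L, 1L, 2L, 2L, 5L))
  expect_equal(r$G, 5L)

  const <- discretize(volume_grid(array(3, c(3, 3, 3))),
                      mask_volume(array(1L, c(3, 3, 3))), 25)
  expect_equal(const$G, 1L)
  expect_true(all(const$levels == 1L))

  shifted <- discretize(volume_grid(v$voxels + 1234), m, 25)
  expect_identical(shifted$levels, r$levels)
  expect_error(discretize(v, mask_volume(array(0L, c(2, 2, 2))), 25), "input error")
  expect_error(discretize(v, m, 0), "parameter error")
})

test_that("GLCM features reproduce hand-worked and degenerate cases", {
  # alternating two-level strip: all co-occurrence mass on (1,2)/(2,1)
  v <- volume_grid(array(c(0, 25, 0, 25, 0, 25), c(6, 1, 1)))
  m <- mask_volume(array(1L, c(6, 1, 1)))
  g <- glcm_features(discretize(v, m, 25))
  expect_equal(g[["JointEntropy"]], 1)
  expect_equal(g[["ClusterShade"]], 0)

  const <- discretize(volume_grid(array(9, c(4, 4, 4))),
                      mask_volume(array(1L, c(4, 4, 4))), 25)
  expect_equal(unname(glcm_features(const)),
               c(0, 0, 0, 1))  # degenerate conventions

  # independence: i.i.d. uniform levels give Imc1 near 0 (exactly 0 when
  # the joint factorizes; sampled case approaches it)
  set.seed(5)
  big <- random_volume(c(12, 12, 12), 55, 0, 100)
  mk <- mask_volume(array(1L, c(12, 12, 12)))
  gi <- glcm_features(discretize(big, mk, 25))
  expect_lt(abs(gi[["Imc1"]]), 0.02)
  expect_lte(gi[["Imc1"]], 0)  # Imc1 <= 0 always
  expect_gte(gi[["MCC"]], 0); expect_lte(gi[["MCC"]], 1)
})

test_that("NGTDM busyness matches hand-enumerated and degenerate cases", {
  # 3x3x1 two-level checkerboard
  vox <- array(matrix(c(0, 25, 0, 25, 0, 25, 0, 25, 0), 3), c(3, 3, 1))
  m <- mask_volume(array(1L, c(3, 3, 1)))
  got <- ngtdm_busyness(discretize(volume_grid(vox), m, 25))
  expect_equal(got, oracle_busyness(vox, m$voxels, 25), tolerance = 1e-12)

  const <- discretize(volume_grid(array(4, c(3, 3, 3))),
                      mask_volume(array(1L, c(3, 3, 3))), 25)
  expect_equal(ngtdm_busyness(const), 0)

  single <- mask_volume(array(c(1L, rep(0L, 26)), c(3, 3, 3)))
  r1 <- discretize(volume_grid(array(50, c(3, 3, 3))), single, 25)
  expect_equal(ngtdm_busyness(r1), 0)
})

test_that("texture features match brute force on random 8^3 fixtures", {
  for (f in 1:8) {
    vox <- random_volume(c(8, 8, 8), 100 + f, 0, 120)$voxels
    set.seed(200 + f)
    mk <- array(as.integer(runif(8^3) < 0.7), c(8, 8, 8))
    if (sum(mk) < 8) mk[1:8] <- 1L
    v <- volume_grid(vox); m <- mask_volume(mk)
    reg <- discretize(v, m, 25)
    got <- glcm_features(reg)
    want <- oracle_glcm(vox, mk, 25)
    for (nm in names(want)) {
      denom <- max(abs(want[[nm]]), 1)
      expect_lt(abs(got[[nm]] - want[[nm]]) / denom, 1e-10,
                label = sprintf("fixture %d %s", f, nm))
    }
    expect_lt(abs(ngtdm_busyness(reg) - oracle_busyness(vox, mk, 25)) /
                max(abs(oracle_busyness(vox, mk, 25)), 1), 1e-10)
    expect_identical(firstorder_minimum(v, m), min(vox[mk == 1]))
  }
})

test_that("texture features are invariant to adding a constant intensity", {
  vox <- random_volume(c(7, 7, 7), 9, 0, 80)$voxels
  m <- mask_volume(array(1L, c(7, 7, 7)))
  a <- glcm_features(discretize(volume_grid(vox), m, 25))
  b <- glcm_features(discretize(volume_grid(vox + 500), m, 25))
  expect_equal(a, b, tolerance = 1e-12)
  expect_equal(ngtdm_busyness(discretize(volume_grid(vox), m, 25)),
               ngtdm_busyness(discretize(volume_grid(vox + 500), m, 25)),
               tolerance = 1e-12)
})

test_that("elongation: ball ~1, 2:1:1 ellipsoid ~0.5, rotation invariant", {
  expect_equal(shape_elongation(ball_mask(10)), 1, tolerance = 0.05)
  e <- ellipsoid_mask(c(20, 10, 10))
  expect_equal(shape_elongation(e), 0.5, tolerance = 0.03)
  # axis permutation is a rigid rotation of the grid
  perm <- mask_volume(aperm(e$voxels, c(3, 1, 2)), e$spacing)
  expect_equal(shape_elongation(perm), shape_elongation(e), tolerance = 0.02)
  flat <- mask_volume(array(c(rep(1L, 9), rep(0L, 18)), c(3, 3, 3)))
  expect_error(shape_elongation(flat), "degenerate-shape")
})

test_that("extract_features composes filter, region and statistic correctly", {
  m <- ball_mask(8, pad = 4)
  set.seed(12)
  v <- volume_grid(array(100 + rnorm(length(m$voxels), sd = 15), dim(m$voxels)))
  band <- make_band(m, band_spec(3, 0))
  fv <- extract_features(v, m, band)
  expect_named(fv, omr_feature_names)
  expect_true(all(is.finite(fv)))
  expect_gt(fv[["original_shape_Elongation"]], 0)
  expect_lte(fv[["original_shape_Elongation"]], 1)
  expect_lte(fv[["logarithm_glcm_Imc1"]], 0)
  expect_gte(fv[["wavelet_HHH_glcm_JointEntropy"]], 0)

  # determinism
  expect_identical(fv, extract_features(v, m, band))
  # the logarithm first-order minimum equals the direct computation
  lg <- logarithm_transform(v)
  expect_equal(fv[["logarithm_firstorder_Minimum"]],
               firstorder_minimum(lg, band), tolerance = 1e-12)
  expect_error(extract_features(v, m, band, registry = "original_glrlm_Foo"),
               "registry error")
})

test_that("shape features are identical across every band spec of a lesion", {
  m <- ellipsoid_mask(c(10, 8, 8), pad = 6)
  set.seed(13)
  v <- volume_grid(array(rnorm(length(m$voxels), 100, 10), dim(m$voxels)))
  specs <- enumerate_band_specs(4)
  ctx <- omrad:::feature_context(v, m, "original_shape_Elongation", 25,
                                 max_outer_mm = 4)
  vals <- vapply(specs, function(sp) {
    idx <- omrad:::band_indices(ctx, sp)
    omrad:::extract_from_context(ctx, idx - 1L)[[1]]
  }, 0)
  expect_equal(length(unique(vals)), 1L)
})

test_that("ICC filter retains by strict threshold with the agreement definition", {
  set.seed(21)
  A <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  same <- icc_filter(A, A)
  expect_true(all(same$icc > 0.999))
  expect_true(all(same$retained))

  B <- matrix(rnorm(100 * 5), 100, 5, dimnames = list(NULL, paste0("g", 1:5)))
  C <- matrix(rnorm(100 * 5), 100, 5, dimnames = list(NULL, paste0("g", 1:5)))
  null <- icc_filter(B, C)
  expect_true(all(abs(null$icc) < 0.35))
  expect_false(any(null$retained))

  # strict inequality at the threshold
  res <- icc_filter(A, A, threshold = 1)
  expect_false(any(res$retained))
  expect_error(icc_filter(A[1:2, ], A[1:2, ]), "insufficient-data")
})
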