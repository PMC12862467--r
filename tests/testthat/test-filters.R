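test_that("logarithm transform fixed points, closed form and monotonicity", {
  z <- volume_grid(array(0, c(4, 4, 4)))
  expect_identical(logarithm_transform(z)$voxels, z$voxels)

  v <- volume_grid(array(c(0, exp(1) - 1, rep(0, 6)), c(2, 2, 2)))
  out <- logarithm_transform(v)
  expect_equal(sort(unique(as.vector(out$voxels))), c(0, exp(1) - 1),
               tolerance = 1e-12)

  set.seed(1)
  w <- volume_grid(array(runif(5^3, 0, 50), c(5, 5, 5)))
  lw <- logarithm_transform(w)
  expect_equal(which.min(lw$voxels), which.min(w$voxels))
  expect_true(all(order(as.vector(lw$voxels)) == order(as.vector(w$voxels))))
})

test_that("LoG kills constants and affine ramps, and matches the Gaussian-blob closed form", {
  const <- volume_grid(array(7, c(20, 20, 20)))
  expect_lt(max(abs(laplacian_of_gaussian(const, 3)$voxels)), 1e-10)

  n <- 31
  ramp <- volume_grid(array(rep(seq_len(n), times = n * n), c(n, n, n)))
  resp <- laplacian_of_gaussian(ramp, 2)$voxels
  core <- resp[10:22, 10:22, 10:22]  # away from borders
  expect_lt(max(abs(core)), 1e-8)

  # centred Gaussian blob: G_s * LoG_sigma at the centre is
  # -3 A s^3 / (s^2 + sigma^2)^(5/2)
  n <- 41; ax <- (0:(n - 1)) - 20; s <- 4; A <- 100
  blob <- A * exp(-outer(outer(ax^2, ax^2, "+"), ax^2, "+") / (2 * s^2))
  got <- laplacian_of_gaussian(volume_grid(array(blob, c(n, n, n))), 3)$voxels[21, 21, 21]
  want <- -3 * A * s^3 / (s^2 + 9)^2.5
  expect_lt(abs(got / want - 1), 0.02)
  expect_lt(got, 0)  # bright blob on dark background: negative centre
  expect_error(laplacian_of_gaussian(const, -1), "parameter error")
})

test_that("LoG is linear", {
  set.seed(3)
  a <- random_volume(c(12, 12, 12), 31)
  b <- random_volume(c(12, 12, 12), 32)
  mix <- volume_grid(2.5 * a$voxels - 1.25 * b$voxels)
  lhs <- laplacian_of_gaussian(mix, 2)$voxels
  rhs <- 2.5 * laplacian_of_gaussian(a, 2)$voxels -
    1.25 * laplacian_of_gaussian(b, 2)$voxels
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-8)
})

test_that("wavelet subbands: constants vanish in H bands, impulse gives the separable kernel", {
  const <- volume_grid(array(5, c(8, 8, 8)))
  sb <- wavelet_subbands(const)
  for (nm in c("LLH", "LHL", "HHL", "HHH"))
    expect_lt(max(abs(sb[[nm]]$voxels)), 1e-10, label = nm)
  # LLL of a constant scales by (sum lo)^3 = 2^(3/2)
  expect_equal(sb$LLL$voxels[4, 4, 4], 5 * 2^1.5, tolerance = 1e-10)

  # unit impulse: subband = outer product of the 1D filters centred there
  n <- 16
  imp <- array(0, c(n, n, n)); imp[8, 8, 8] <- 1
  got <- wavelet_subbands(volume_grid(imp), "LHL")$LHL$voxels
  lo <- omrad:::coif1_lo; hi <- omrad:::coif1_hi
  c0 <- (length(lo) - 1) %/% 2
  want <- array(0, c(n, n, n))
  for (t1 in seq_along(lo)) for (t2 in seq_along(hi)) for (t3 in seq_along(lo)) {
    # y[i] = sum_t h[t] x[i + c - t]: the impulse at 8 contributes to
    # i = 8 + t - 1 - c per axis (periodic)
    i <- ((8 + (t1 - 1) - c0 - 1) %% n) + 1
    j <- ((8 + (t2 - 1) - c0 - 1) %% n) + 1
    k <- ((8 + (t3 - 1) - c0 - 1) %% n) + 1
    want[i, j, k] <- want[i, j, k] + lo[t1] * hi[t2] * lo[t3]
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("wavelet transform is deterministic, shape-preserving and invertible", {
  v <- random_volume(c(10, 12, 14), 77)
  sb1 <- wavelet_subbands(v)
  sb2 <- wavelet_subbands(v)
  expect_identical(sb1$HHH$voxels, sb2$HHH$voxels)
  expect_identical(dim(sb1$LHH$voxels), dim(v$voxels))
  rec <- wavelet_reconstruct(sb1)
  expect_lt(max(abs(rec$voxels - v$voxels)) / max(abs(v$voxels)), 1e-6)
  # re-applying the transform to LLL is well-defined
  expect_silent(wavelet_subbands(sb1$LLL, "LLL"))
  expect_error(wavelet_subbands(volume_grid(array(0, c(4, 4, 4)))),
               "input-too-small")
})
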