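# Small geometric fixtures built in code.

ball_mask <- function(radius_mm, spacing = 1, pad = 2) {
  half <- ceiling(radius_mm / spacing) + pad
  n <- 2L * as.integer(half) + 1L
  ax <- ((0:(n - 1)) - half) * spacing
  inside <- outer(outer(ax^2, ax^2, "+"), ax^2, "+") <= radius_mm^2
  mask_volume(array(as.integer(inside), c(n, n, n)), rep(spacing, 3))
}

ellipsoid_mask <- function(semi_axes, spacing = 1, pad = 2) {
  half <- ceiling(max(semi_axes) / spacing) + pad
  n <- 2L * as.integer(half) + 1L
  ax <- ((0:(n - 1)) - half) * spacing
  e <- outer(outer((ax / semi_axes[1])^2, (ax / semi_axes[2])^2, "+"),
             (ax / semi_axes[3])^2, "+") <= 1
  mask_volume(array(as.integer(e), c(n, n, n)), rep(spacing, 3))
}

random_volume <- function(dims, seed, lo = 0, hi = 100) {
  set.seed(seed)
  volume_grid(array(runif(prod(dims), lo, hi), dims))
}

# feature matrix with planted informative columns, for chain tests
tabular_cohort <- function(n, p, informative = integer(0), beta = 1,
                           seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  eta <- if (length(informative)) X[, informative, drop = FALSE] %*%
    rep(beta, length(informative)) else rep(0, n)
  y <- rbinom(n, 1, plogis(as.vector(eta)))
  list(X = as.data.frame(X), y = y)
}

# features_by_spec built from tabular noise (no images), for search tests.
# `signal` > 0 embeds a patient-level latent effect into f1 of every spec so
# models have something to select; signal = 0 gives a pure null.
tabular_features_by_spec <- function(n, p, specs, seed = 1,
                                     cohorts = c(0.6, 0.2, 0.2),
                                     signal = 0.8) {
  set.seed(seed)
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(signal * z))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  ch <- sample(rep(c("training", "internal_test", "external_test"),
                   round(n * cohorts))[seq_len(n)])
  out <- lapply(specs, function(sp) {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    if (signal > 0) X[, 1] <- X[, 1] + z
    df <- data.frame(patient_id = sprintf("P%03d", seq_len(n)), label = y,
                     cohort = ch, X, stringsAsFactors = FALSE)
    attr(df, "spec") <- sp
    df
  })
  names(out) <- vapply(specs, function(s) omrad:::spec_label(s), "")
  out
}
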