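# The curated feature set: the seven margin-region signature features.
# Intensity features are computed on the band; the shape feature always on
# the original lesion mask.

#' The seven curated margin-region feature names
#'
#' Canonical names of the curated radiomics signature features. Each name
#' encodes intensity filter, feature class and statistic.
#'
#' @format Character vector of length 7.
#' @export
omr_feature_names <- c(
  "logarithm_firstorder_Minimum",
  "logarithm_glcm_Imc1",
  "original_shape_Elongation",
  "wavelet_LHL_glcm_MCC",
  "wavelet_HLH_ngtdm_Busyness",
  "log_sigma_3_0_mm_3D_glcm_ClusterShade",
  "wavelet_HHH_glcm_JointEntropy"
)

#' Discretize a masked region into gray levels
#'
#' Min-anchored fixed-bin-width discretization:
#' `level(v) = floor((x(v) - min) / bin_width) + 1`, so levels span `1..G`
#' with `G = floor((max - min)/bin_width) + 1`. Adding a constant to all
#' intensities leaves the levels unchanged, which makes every downstream
#' texture feature shift-invariant.
#'
#' @param vol a [volume_grid()].
#' @param mask a nonempty [mask_volume()] paired with `vol`.
#' @param bin_width positive bin width in intensity units (default 25, the
#'   package-wide texture default).
#' @return A list of class `discretized_region` with 0-based linear voxel
#'   indices `idx`, integer `levels`, level count `G`, `bin_width` and `dim`.
#' @export
discretize <- function(vol, mask, bin_width = 25) {
  check_paired(vol, mask)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("parameter error: bin_width must be positive", call. = FALSE)
  sel <- which(mask$voxels != 0)
  if (length(sel) == 0) stop("input error: empty mask", call. = FALSE)
  x <- vol$voxels[sel]
  lev <- as.integer(floor((x - min(x)) / bin_width)) + 1L
  structure(list(idx = sel - 1L, levels = lev, G = max(lev),
                 bin_width = bin_width, dim = as.integer(dim(vol$voxels))),
            class = "discretized_region")
}

#' GLCM texture features of a discretized region
#'
#' Symmetric gray-level co-occurrence matrices at Chebyshev distance 1 over
#' the 13 unique 3D directions, normalized per direction; each feature is
#' computed per direction and averaged over directions that contain at
#' least one co-occurring pair. Definitions: `JointEntropy = -sum p log2 p`;
#' `ClusterShade = sum (i + j - mu_i - mu_j)^3 p(i,j)`;
#' `Imc1 = (HXY - HXY1) / max(HX, HY)` with `HXY` the joint entropy and
#' `HXY1 = -sum p(i,j) log2(px(i) py(j))`; `MCC` is the square root of the
#' second-largest eigenvalue of
#' `Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k))`.
#' A single-level region returns the degenerate conventions
#' `JointEntropy = 0`, `ClusterShade = 0`, `Imc1 = 0`, `MCC = 1`.
#'
#' @param region a `discretized_region` from [discretize()].
#' @param stats which of the four statistics to compute (MCC is the only
#'   one needing an eigendecomposition).
#' @return Named numeric vector with the requested statistics.
#' @export
glcm_features <- function(region, stats = c("JointEntropy", "ClusterShade",
                                            "Imc1", "MCC")) {
  if (!inherits(region, "discretized_region"))
    stop("region must come from discretize()", call. = FALSE)
  degenerate <- c(JointEntropy = 0, ClusterShade = 0, Imc1 = 0, MCC = 1)[stats]
  if (region$G == 1L) return(degenerate)
  out <- cpp_glcm_stats(region$idx, region$levels, region$dim, region$G,
                        "MCC" %in% stats)
  out[stats]
}

#' NGTDM busyness of a discretized region
#'
#' With `p_i` the level probabilities and `s_i` the summed absolute
#' difference between level `i` voxels and the mean of their valid
#' 26-neighbours (neighbours outside the region are excluded),
#' `Busyness = sum_i p_i s_i / sum_{i,j} |i p_i - j p_j|` over levels with
#' positive probability. A zero denominator (single occupied level) returns
#' 0 by convention; so does a single-voxel region, whose `s_i` are all 0.
#'
#' @param region a `discretized_region` from [discretize()].
#' @return A single number.
#' @export
ngtdm_busyness <- function(region) {
  if (!inherits(region, "discretized_region"))
    stop("region must come from discretize()", call. = FALSE)
  if (length(region$idx) == 0) stop("input error: empty region", call. = FALSE)
  m <- cpp_ngtdm(region$idx, region$levels, region$dim, region$G)
  n_i <- m[, 1]; s_i <- m[, 2]
  N <- sum(n_i)
  p <- n_i / N
  lv <- seq_len(region$G)
  occ <- p > 0
  ip <- (lv * p)[occ]
  denom <- sum(abs(outer(ip, ip, "-")))
  if (denom == 0) return(0)
  sum(p * s_i) / denom
}

#' Minimum intensity over a masked region
#'
#' @param vol a [volume_grid()] (typically a filtered volume).
#' @param mask a nonempty [mask_volume()] paired with `vol`.
#' @return A single number.
#' @export
firstorder_minimum <- function(vol, mask) {
  check_paired(vol, mask)
  sel <- mask$voxels != 0
  if (!any(sel)) stop("input error: empty mask", call. = FALSE)
  min(vol$voxels[sel])
}

firstorder_stat <- function(vol, mask, stat) {
  check_paired(vol, mask)
  sel <- mask$voxels != 0
  if (!any(sel)) stop("input error: empty mask", call. = FALSE)
  x <- vol$voxels[sel]
  switch(stat,
         Minimum = min(x), Maximum = max(x), Mean = mean(x),
         Variance = stats::var(x) * (length(x) - 1) / length(x),
         stop("registry error: unknown first-order statistic ", stat,
              call. = FALSE))
}

#' Elongation of a lesion mask
#'
#' With `l1 >= l2 >= l3` the eigenvalues of the covariance of in-mask voxel
#' physical coordinates, elongation is `sqrt(l2 / l1)`: 1 for a sphere,
#' approaching 0 for a needle. Always computed on the original lesion mask,
#' never on a margin band.
#'
#' @param mask a [mask_volume()] with at least 4 non-coplanar voxels.
#' @return A value in `(0, 1]`.
#' @export
shape_elongation <- function(mask) {
  sel <- which(mask$voxels != 0)
  if (length(sel) < 4)
    stop("degenerate-shape error: need >= 4 in-mask voxels", call. = FALSE)
  d <- dim(mask$voxels)
  idx0 <- sel - 1L
  co <- cbind(idx0 %% d[1],
              (idx0 %/% d[1]) %% d[2],
              idx0 %/% (d[1] * d[2]))
  xyz <- sweep(co, 2, mask$spacing, "*")
  ev <- sort(eigen(stats::cov(xyz), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  if (ev[3] <= 1e-12 * max(ev[1], 1))
    stop("degenerate-shape error: coplanar or collinear mask", call. = FALSE)
  sqrt(ev[2] / ev[1])
}

# ---------------------------------------------------------------- registry

parse_feature_name <- function(name) {
  if (grepl("^log_sigma_", name)) {
    m <- regmatches(name, regexec("^(log_sigma_([0-9]+)_([0-9]+)_mm_3D)_([a-z]+)_(\\w+)$", name))[[1]]
    if (length(m) == 0) stop("registry error: unknown feature name ", name, call. = FALSE)
    return(list(filter = "log_sigma",
                sigma = as.numeric(paste0(m[3], ".", m[4])),
                class = m[5], stat = m[6]))
  }
  m <- regmatches(name, regexec("^(original|logarithm|wavelet_([LH]{3}))_([a-z]+)_(\\w+)$", name))[[1]]
  if (length(m) == 0) stop("registry error: unknown feature name ", name, call. = FALSE)
  filt <- if (m[3] != "") "wavelet" else m[2]
  list(filter = filt, subband = if (m[3] != "") m[3] else NULL,
       class = m[4], stat = m[5])
}

# Precompute everything shared across band specs of one patient: filtered
# volumes and the two distance maps. Filters run on the whole volume before
# masking.
feature_context <- function(vol, lesion_mask, registry = omr_feature_names,
                            bin_width = 25, max_outer_mm = 10) {
  check_paired(vol, lesion_mask)
  if (!is_isotropic(vol))
    stop("precondition error: feature extraction requires an isotropic grid",
         call. = FALSE)
  parsed <- lapply(registry, parse_feature_name)
  names(parsed) <- registry
  vols <- list(original = vol)
  subbands <- unique(unlist(lapply(parsed, function(p) p$subband)))
  if (length(subbands)) {
    wb <- wavelet_subbands(vol, subbands)
    for (nm in subbands) vols[[paste0("wavelet_", nm)]] <- wb[[nm]]
  }
  if (any(vapply(parsed, function(p) p$filter == "logarithm", TRUE)))
    vols$logarithm <- logarithm_transform(vol)
  sigmas <- unique(unlist(lapply(parsed, function(p) p$sigma)))
  for (s in sigmas)
    vols[[sprintf("log_sigma_%g", s)]] <- laplacian_of_gaussian(vol, s)
  maps <- band_distance_maps(lesion_mask)
  # flat index vectors so per-spec band selection is a cheap subset: the
  # in-lesion voxels with their depth, and the near-outside shell with its
  # distance to the lesion
  idx_in <- which(maps$inside)
  din2_in <- maps$din2[idx_in]
  idx_out <- which(!maps$inside & maps$dout2 <= max_outer_mm^2)
  dout2_out <- maps$dout2[idx_out]
  # volume key -> GLCM stats wanted, so each co-occurrence matrix is built
  # (and its eigendecomposition run) at most once per band
  glcm_want <- list()
  for (nm in names(parsed)) {
    p <- parsed[[nm]]
    if (p$class == "glcm") {
      key <- context_key(p)
      glcm_want[[key]] <- unique(c(glcm_want[[key]], p$stat))
    }
  }
  list(vols = vols, parsed = parsed, bin_width = bin_width,
       lesion_mask = lesion_mask, maps = maps,
       idx_in = idx_in, din2_in = din2_in,
       idx_out = idx_out, dout2_out = dout2_out,
       glcm_want = glcm_want, memo = new.env(parent = emptyenv()))
}

context_key <- function(p) {
  switch(p$filter,
         original = "original",
         logarithm = "logarithm",
         wavelet = paste0("wavelet_", p$subband),
         log_sigma = sprintf("log_sigma_%g", p$sigma))
}

# 1-based linear voxel indices of a band, from the precomputed context
band_indices <- function(ctx, spec) {
  if (spec$is_original) return(ctx$idx_in)
  sel <- integer(0)
  if (spec$inner_mm > 0)
    sel <- ctx$idx_in[ctx$din2_in <= spec$inner_mm^2]
  if (spec$outer_mm > 0)
    sel <- c(sel, ctx$idx_out[ctx$dout2_out <= spec$outer_mm^2])
  sel
}

context_volume <- function(ctx, p) ctx$vols[[context_key(p)]]

extract_from_context <- function(ctx, band_idx0) {
  # band_idx0: 0-based linear indices of band voxels
  out <- numeric(length(ctx$parsed))
  names(out) <- names(ctx$parsed)
  dim3 <- as.integer(dim(ctx$lesion_mask$voxels))
  known_stats <- c("JointEntropy", "ClusterShade", "Imc1", "MCC")
  idx1 <- band_idx0 + 1L
  region_cache <- list()
  get_region <- function(key) {
    r <- region_cache[[key]]
    if (!is.null(r)) return(r)
    x <- ctx$vols[[key]]$voxels[idx1]
    lev <- as.integer(floor((x - min(x)) / ctx$bin_width)) + 1L
    r <- structure(list(idx = band_idx0, levels = lev, G = max(lev),
                        bin_width = ctx$bin_width, dim = dim3),
                   class = "discretized_region")
    region_cache[[key]] <<- r
    r
  }
  glcm_cache <- list()
  for (nm in names(ctx$parsed)) {
    p <- ctx$parsed[[nm]]
    if (p$class == "shape") {
      if (p$stat != "Elongation")
        stop("registry error: unknown shape statistic ", p$stat, call. = FALSE)
      if (is.null(ctx$memo$elongation))  # lesion shape is band-independent
        ctx$memo$elongation <- shape_elongation(ctx$lesion_mask)
      out[nm] <- ctx$memo$elongation
      next
    }
    key <- context_key(p)
    if (p$class == "firstorder") {
      out[nm] <- firstorder_stat_idx(ctx$vols[[key]], idx1, p$stat)
    } else if (p$class == "glcm") {
      if (!p$stat %in% known_stats)
        stop("registry error: unknown GLCM statistic ", p$stat, call. = FALSE)
      gl <- glcm_cache[[key]]
      if (is.null(gl)) {
        gl <- glcm_features(get_region(key), ctx$glcm_want[[key]])
        glcm_cache[[key]] <- gl
      }
      out[nm] <- gl[[p$stat]]
    } else if (p$class == "ngtdm") {
      if (p$stat != "Busyness")
        stop("registry error: unknown NGTDM statistic ", p$stat, call. = FALSE)
      out[nm] <- ngtdm_busyness(get_region(key))
    } else {
      stop("registry error: unknown feature class ", p$class, call. = FALSE)
    }
  }
  out
}

firstorder_stat_idx <- function(vol, idx1, stat) {
  x <- vol$voxels[idx1]
  switch(stat,
         Minimum = min(x), Maximum = max(x), Mean = mean(x),
         Variance = stats::var(x) * (length(x) - 1) / length(x),
         stop("registry error: unknown first-order statistic ", stat,
              call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the named radiomics features for one band
#'
#' Each feature name encodes its intensity filter, feature class and
#' statistic (e.g. `wavelet_HHH_glcm_JointEntropy`). Intensity features are
#' computed on the band mask; shape features on the original lesion mask.
#' Deterministic for fixed inputs and configuration.
#'
#' @param vol a [volume_grid()] on an isotropic grid.
#' @param lesion_mask the original lesion [mask_volume()].
#' @param band the band [mask_volume()] (may equal `lesion_mask`).
#' @param registry character vector of feature names (default the seven
#'   curated names in [omr_feature_names]).
#' @param bin_width texture discretization bin width (default 25).
#' @return Named numeric vector, one value per registry entry.
#' @export
extract_features <- function(vol, lesion_mask, band,
                             registry = omr_feature_names, bin_width = 25) {
  check_paired(vol, band)
  if (sum(band$voxels) == 0)
    stop("input error: empty band mask", call. = FALSE)
  ctx <- feature_context(vol, lesion_mask, registry, bin_width)
  extract_from_context(ctx, which(band$voxels != 0) - 1L)
}

# --------------------------------------------------------------- ICC filter

icc_a1 <- function(x, y) {
  # two-way random effects, absolute agreement, single measurement: ICC(A,1)
  S <- cbind(x, y)
  n <- nrow(S); k <- 2
  m <- mean(S)
  Ri <- rowMeans(S); Cj <- colMeans(S)
  MSR <- k * sum((Ri - m)^2) / (n - 1)
  MSC <- n * sum((Cj - m)^2) / (k - 1)
  MSE <- sum((S - outer(Ri, rep(1, k)) - outer(rep(1, n), Cj) + m)^2) /
    ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  if (denom == 0) return(1)
  (MSR - MSE) / denom
}

#' Reproducibility filter by intraclass correlation
#'
#' Computes the two-way random-effects, absolute-agreement,
#' single-measurement ICC per feature between two raters' feature matrices
#' and retains features with ICC strictly greater than the threshold.
#'
#' @param rater_a,rater_b data frames or matrices of matched patients
#'   (rows) by identical feature names (columns); row order must match.
#' @param threshold retention threshold (default 0.75); retention is strict
#'   (`ICC > threshold`).
#' @return A data.frame with `feature`, `icc`, `retained`.
#' @export
icc_filter <- function(rater_a, rater_b, threshold = 0.75) {
  a <- as.matrix(rater_a); b <- as.matrix(rater_b)
  if (!identical(colnames(a), colnames(b)))
    stop("input error: feature names differ between raters", call. = FALSE)
  if (nrow(a) != nrow(b))
    stop("input error: patient counts differ between raters", call. = FALSE)
  if (nrow(a) < 3)
    stop("insufficient-data error: need >= 3 shared patients", call. = FALSE)
  icc <- vapply(seq_len(ncol(a)), function(j) icc_a1(a[, j], b[, j]), 0)
  data.frame(feature = colnames(a), icc = icc, retained = icc > threshold,
             stringsAsFactors = FALSE)
}
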