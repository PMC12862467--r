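# Intensity-domain filters applied to the whole volume before any masking:
# texture near a band border needs spatial context, so filtering after
# masking would bias boundary voxels.

#' Signed logarithm intensity transform
#'
#' `y = sign(x) * log(|x| + 1)`, rescaled by `max|x| / max|y|` so the output
#' magnitude range matches the input magnitude range. An all-zero volume
#' maps to itself. The transform is order-preserving on nonnegative input,
#' so the location of the in-mask minimum is unchanged.
#'
#' @param vol a [volume_grid()].
#' @return A [volume_grid()] of the same shape.
#' @export
logarithm_transform <- function(vol) {
  x <- vol$voxels
  mx <- max(abs(x))
  if (mx == 0) return(vol)
  y <- sign(x) * log1p(abs(x))
  my <- max(abs(y))
  if (my > 0) y <- y * (mx / my)
  volume_grid(y, vol$spacing, vol$origin)
}

gauss_kernel_1d <- function(sigma_vox, order = 0L) {
  r <- max(1L, as.integer(ceiling(3.5 * sigma_vox)))
  t <- (-r):r
  g <- exp(-t^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  # sampled second derivative of the (normalized) Gaussian, DC-corrected so
  # that constants map exactly to zero
  g2 <- g * (t^2 - sigma_vox^2) / sigma_vox^4
  g2 - mean(g2)
}

#' Laplacian-of-Gaussian filter
#'
#' Response `del^2 (G_sigma * vol)` with `sigma` given in millimetres and
#' converted to voxels through the grid spacing. Computed as the sum over
#' axes of separable convolutions with a sampled Gaussian second derivative
#' along one axis and sampled Gaussians along the others (mirror boundary).
#' Sign convention: a bright blob on a dark background yields a negative
#' response at its centre.
#'
#' @param vol a [volume_grid()] on an isotropic grid.
#' @param sigma_mm positive Gaussian scale in mm (the curated feature set
#'   uses 3.0 mm).
#' @return A [volume_grid()] of the same shape.
#' @export
laplacian_of_gaussian <- function(vol, sigma_mm = 3.0) {
  if (!is.numeric(sigma_mm) || length(sigma_mm) != 1L || sigma_mm <= 0)
    stop("parameter error: sigma_mm must be positive", call. = FALSE)
  if (!is_isotropic(vol))
    stop("precondition error: LoG requires an isotropic grid", call. = FALSE)
  sv <- sigma_mm / vol$spacing[1]
  g <- gauss_kernel_1d(sv, 0L)
  g2 <- gauss_kernel_1d(sv, 2L) / vol$spacing[1]^2  # response per mm^2
  d <- as.integer(dim(vol$voxels))
  acc <- cpp_conv_sep(vol$voxels, d, g2, g, g, 0L) +
         cpp_conv_sep(vol$voxels, d, g, g2, g, 0L) +
         cpp_conv_sep(vol$voxels, d, g, g, g2, 0L)
  volume_grid(array(acc, d), vol$spacing, vol$origin)
}

# Coiflet-1 decomposition filters (orthonormal; low-pass sums to sqrt(2),
# high-pass sums to 0 so constants vanish in every H subband).
coif1_lo <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
              0.852572020212255, 0.337897662457809, -0.072732619512854)
coif1_hi <- c(0.072732619512854, 0.337897662457809, -0.852572020212255,
              0.384864846864203, 0.072732619512854, -0.015655728135465)

#' Single-level stationary 3D wavelet subbands
#'
#' Undecimated (stationary) separable 3D transform with the Coiflet-1 filter
#' pair and periodic boundary handling; every subband has the shape of the
#' input. Subband names are three letters, the first letter naming the
#' filter (L = low-pass, H = high-pass) applied along the first array axis,
#' the second letter the second axis, and so on.
#'
#' @param vol a [volume_grid()] on an isotropic grid.
#' @param bands character vector of subband names to compute (default all
#'   eight, `"LLL"` ... `"HHH"`).
#' @return Named list of [volume_grid()] objects.
#' @export
wavelet_subbands <- function(vol, bands = NULL) {
  if (!is_isotropic(vol))
    stop("precondition error: wavelet transform requires an isotropic grid",
         call. = FALSE)
  d <- as.integer(dim(vol$voxels))
  if (any(d < length(coif1_lo)))
    stop("input-too-small error: every extent must be >= filter length (",
         length(coif1_lo), ")", call. = FALSE)
  all_names <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  if (is.null(bands)) bands <- all_names
  if (!all(bands %in% all_names))
    stop("unknown wavelet subband name(s): ",
         paste(setdiff(bands, all_names), collapse = ", "), call. = FALSE)
  pick <- function(ch) if (ch == "L") coif1_lo else coif1_hi
  out <- lapply(bands, function(nm) {
    ch <- strsplit(nm, "")[[1]]
    y <- cpp_conv_sep(vol$voxels, d, pick(ch[1]), pick(ch[2]), pick(ch[3]), 1L)
    volume_grid(array(y, d), vol$spacing, vol$origin)
  })
  names(out) <- bands
  out
}

#' Reconstruct a volume from its stationary wavelet subbands
#'
#' Applies the adjoint (synthesis) filters to each of the eight subbands and
#' averages; for the orthonormal Coiflet-1 pair under periodic boundaries
#' this reproduces the input exactly (up to floating-point error).
#'
#' @param subbands named list of all 8 subbands from [wavelet_subbands()].
#' @return A [volume_grid()].
#' @export
wavelet_reconstruct <- function(subbands) {
  all_names <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  if (!all(all_names %in% names(subbands)))
    stop("reconstruction needs all 8 subbands", call. = FALSE)
  ref <- subbands[[1]]
  d <- as.integer(dim(ref$voxels))
  # adjoint of analysis: reversed filter, padded to odd length so the fixed
  # centre anchor lands on the required alignment
  syn <- function(h) c(rev(h), 0)
  pick <- function(ch) if (ch == "L") syn(coif1_lo) else syn(coif1_hi)
  acc <- array(0, d)
  for (nm in all_names) {
    ch <- strsplit(nm, "")[[1]]
    acc <- acc + cpp_conv_sep(subbands[[nm]]$voxels, d,
                              pick(ch[1]), pick(ch[2]), pick(ch[3]), 1L)
  }
  volume_grid(acc / 8, ref$spacing, ref$origin)
}
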