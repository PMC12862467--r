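#' 3D scalar image volume with physical spacing
#'
#' A `volume_grid` couples a 3D numeric array of voxel intensities with the
#' physical geometry of its grid. Voxel indices are 0-based in the geometry
#' convention: the physical position of voxel `(i, j, k)` (0-based) is
#' `origin + c(i, j, k) * spacing`, with array axes 1, 2, 3 mapping to
#' physical x, y, z. All band widths in this package are millimetres, so
#' spacing is in mm per axis.
#'
#' @param voxels 3D numeric array of finite intensities.
#' @param spacing numeric length-3, mm per axis; all components positive.
#' @param origin numeric length-3, mm offset of the first voxel centre.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array, got ", length(dim(voxels)), " dimensions",
         call. = FALSE)
  if (any(dim(voxels) < 1L)) stop("all extents must be positive", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive reals", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite reals", call. = FALSE)
  if (any(!is.finite(voxels)))
    stop("voxel values must all be finite", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' Binary mask on a volume grid
#'
#' A `mask_volume` is a `volume_grid` whose voxels are restricted to
#' \{0, 1\}; it marks a lesion or margin-band region.
#'
#' @inheritParams volume_grid
#' @param empty_ok allow an all-zero mask (used for degenerate bands).
#' @return An object of class `mask_volume` (inherits `volume_grid`).
#' @export
mask_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        empty_ok = TRUE) {
  if (is.logical(voxels)) {
    storage.mode(voxels) <- "integer"
  }
  if (!all(voxels %in% c(0, 1)))
    stop("mask values must be in {0, 1}", call. = FALSE)
  v <- volume_grid(voxels, spacing, origin)
  if (!empty_ok && sum(voxels) == 0)
    stop("mask is empty", call. = FALSE)
  v$nonempty <- sum(voxels) > 0
  class(v) <- c("mask_volume", "volume_grid")
  v
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              class(x)[1], paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x"),
              paste(format(x$origin, digits = 4), collapse = ",")))
  if (inherits(x, "mask_volume"))
    cat(sprintf("  in-mask voxels: %d\n", sum(x$voxels)))
  invisible(x)
}

is_isotropic <- function(vol, tol = 1e-8) {
  diff(range(vol$spacing)) <= tol * max(vol$spacing)
}

check_paired <- function(vol, mask) {
  if (!identical(dim(vol$voxels), dim(mask$voxels)))
    stop("pairing error: image and mask shapes differ (",
         paste(dim(vol$voxels), collapse = "x"), " vs ",
         paste(dim(mask$voxels), collapse = "x"), ")", call. = FALSE)
  if (max(abs(vol$spacing - mask$spacing)) > 1e-6 ||
      max(abs(vol$origin - mask$origin)) > 1e-6)
    stop("pairing error: image and mask grids differ", call. = FALSE)
  invisible(TRUE)
}

# ------------------------------------------------------------------ file IO

nrrd_type_map <- c(
  "double" = "double", "float" = "float",
  "int" = "int32", "int32" = "int32", "signed int" = "int32",
  "short" = "int16", "int16" = "int16",
  "uchar" = "uint8", "unsigned char" = "uint8", "uint8" = "uint8"
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic))
    stop("format error: not an NRRD file: ", path, call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("format error: truncated NRRD header", call. = FALSE)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ": ?", fixed = FALSE)[[1]]
    fields[[tolower(kv[1])]] <- paste(kv[-1], collapse = ":")
  }
  ndim <- as.integer(fields[["dimension"]])
  if (is.na(ndim) || ndim != 3L)
    stop("dimensionality error: expected 3D NRRD, got dimension ", ndim, call. = FALSE)
  sizes <- as.integer(strsplit(trimws(fields[["sizes"]]), "\\s+")[[1]])
  enc <- tolower(trimws(fields[["encoding"]]))
  if (enc != "raw") stop("format error: only raw NRRD encoding supported", call. = FALSE)
  type <- nrrd_type_map[tolower(trimws(fields[["type"]]))]
  if (is.na(type)) stop("format error: unsupported NRRD type", call. = FALSE)
  endian <- if (!is.null(fields[["endian"]])) trimws(fields[["endian"]]) else "little"
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(vecs, function(s)
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]]), numeric(3)))
    off <- m; diag(off) <- 0
    if (any(abs(off) > 1e-6 * max(abs(m))))
      stop("format error: oblique NRRD space directions not supported", call. = FALSE)
    spacing <- abs(diag(m))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(trimws(fields[["spacings"]]), "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  n <- prod(sizes)
  vox <- switch(type,
    double = readBin(con, "double", n = n, size = 8, endian = endian),
    float  = readBin(con, "double", n = n, size = 4, endian = endian),
    int32  = as.double(readBin(con, "integer", n = n, size = 4, endian = endian)),
    int16  = as.double(readBin(con, "integer", n = n, size = 2, endian = endian)),
    uint8  = as.double(readBin(con, "integer", n = n, size = 1, signed = FALSE,
                               endian = endian)))
  if (length(vox) != n) stop("format error: truncated NRRD data", call. = FALSE)
  volume_grid(array(vox, sizes), spacing, origin)
}

write_nrrd <- function(vol, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(vol$voxels)
  hdr <- c(
    "NRRD0004",
    "# written by omrad",
    "type: double",
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            vol$origin[1], vol$origin[2], vol$origin[3]),
    "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(vol$voxels, mode = "double"), con, size = 8,
           endian = "little")
  invisible(path)
}

read_nifti_grid <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.vector(img), d[1:3])
    d <- d[1:3]
  } else if (length(d) != 3L) {
    stop("dimensionality error: expected 3D image, got ", length(d), "D", call. = FALSE)
  } else {
    img2 <- array(as.vector(img), d)
  }
  xf <- try(RNifti::xform(img), silent = TRUE)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- c(0, 0, 0)
  if (!inherits(xf, "try-error")) {
    m <- unclass(xf)[1:3, 1:3, drop = FALSE]
    sp <- sqrt(colSums(m^2))
    if (all(sp > 0)) spacing <- sp
    origin <- unclass(xf)[1:3, 4]
  }
  volume_grid(img2, spacing, origin)
}

write_nifti_grid <- function(vol, path) {
  img <- RNifti::asNifti(vol$voxels, pixdim = vol$spacing)
  aff <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D volume from NIfTI or NRRD
#'
#' Spacing and origin are taken from the file header (NIfTI sform/pixdim, or
#' NRRD `space directions`/`space origin`); intensities are unmodified. Only
#' axis-aligned grids are supported.
#'
#' @param path path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path, call. = FALSE)
  lp <- tolower(path)
  if (grepl("\\.nrrd$", lp)) read_nrrd(path)
  else if (grepl("\\.nii(\\.gz)?$", lp)) read_nifti_grid(path)
  else stop("format error: unrecognized image extension: ", path, call. = FALSE)
}

#' Read a binary mask from NIfTI or NRRD
#'
#' @inheritParams read_volume
#' @return A [mask_volume()]; errors if the file holds values outside \{0, 1\}.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  mask_volume(array(as.integer(round(v$voxels)), dim(v$voxels)),
              v$spacing, v$origin)
}

#' Write a volume or mask to NIfTI or NRRD
#'
#' The format is chosen from the file extension. Round trips preserve
#' voxels, spacing and origin exactly.
#'
#' @param vol a [volume_grid()] or [mask_volume()].
#' @param path output path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @export
write_volume <- function(vol, path) {
  lp <- tolower(path)
  if (grepl("\\.nrrd$", lp)) write_nrrd(vol, path)
  else if (grepl("\\.nii(\\.gz)?$", lp)) write_nifti_grid(vol, path)
  else stop("format error: unrecognized image extension: ", path, call. = FALSE)
}

# ---------------------------------------------------------------- resampling

#' Resample a volume to isotropic spacing
#'
#' Millimetre band widths are only well defined on an isotropic grid, so all
#' margin geometry and feature extraction run after resampling (the package
#' default is 1 mm, making mm equal to voxel). Output extent per axis is
#' `round(extent * spacing / target_mm)`; `continuous` uses trilinear
#' interpolation, `nearest` preserves the value set and is required for
#' masks. An input already isotropic at the target is returned unchanged.
#'
#' @param vol a [volume_grid()] or [mask_volume()].
#' @param target_mm positive target spacing in mm.
#' @param mode `"continuous"` (trilinear) or `"nearest"`.
#' @return A resampled object of the same class.
#' @export
resample_isotropic <- function(vol, target_mm = 1,
                               mode = c("continuous", "nearest")) {
  mode <- match.arg(mode)
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("parameter error: target_mm must be a positive real", call. = FALSE)
  d <- dim(vol$voxels)
  if (max(abs(vol$spacing - target_mm)) < 1e-9) return(vol)
  nd <- pmax(1L, as.integer(round(d * vol$spacing / target_mm)))

  # source (0-based, fractional) index per output index, per axis
  src <- lapply(1:3, function(a) (seq_len(nd[a]) - 1) * target_mm / vol$spacing[a])
  if (mode == "nearest") {
    ix <- pmin(pmax(as.integer(round(src[[1]])), 0L), d[1] - 1L) + 1L
    iy <- pmin(pmax(as.integer(round(src[[2]])), 0L), d[2] - 1L) + 1L
    iz <- pmin(pmax(as.integer(round(src[[3]])), 0L), d[3] - 1L) + 1L
    out <- vol$voxels[ix, iy, iz, drop = FALSE]
  } else {
    lo <- hi <- w <- vector("list", 3)
    for (a in 1:3) {
      s <- pmin(pmax(src[[a]], 0), d[a] - 1)
      lo[[a]] <- pmin(floor(s), d[a] - 1)
      hi[[a]] <- pmin(lo[[a]] + 1, d[a] - 1)
      w[[a]] <- s - lo[[a]]
    }
    out <- array(0, nd)
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
      gx <- (if (cx) hi[[1]] else lo[[1]]) + 1L
      gy <- (if (cy) hi[[2]] else lo[[2]]) + 1L
      gz <- (if (cz) hi[[3]] else lo[[3]]) + 1L
      wx <- if (cx) w[[1]] else 1 - w[[1]]
      wy <- if (cy) w[[2]] else 1 - w[[2]]
      wz <- if (cz) w[[3]] else 1 - w[[3]]
      wt <- outer(outer(wx, wy), wz)
      if (any(wt > 0))
        out <- out + wt * vol$voxels[gx, gy, gz, drop = FALSE]
    }
  }
  if (inherits(vol, "mask_volume"))
    mask_volume(array(as.integer(round(out)), nd), rep(target_mm, 3), vol$origin)
  else
    volume_grid(out, rep(target_mm, 3), vol$origin)
}
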