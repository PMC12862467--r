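#' Margin-band specification
#'
#' A margin band around a lesion is parameterized by an inward erosion depth
#' `inner_mm` and an outward expansion distance `outer_mm`, both integer
#' millimetres. The band is `dilate(mask, outer_mm)` set-minus
#' `erode(mask, inner_mm)` with a Euclidean ball structuring element, so
#' `(inner 5, outer 0)` is the inner 5 mm rim of the lesion. The unmodified
#' lesion is represented by a distinct `is_original` spec, not by the
#' degenerate `(0, 0)` pair (which is the empty set).
#'
#' @param inner_mm integer erosion depth in mm.
#' @param outer_mm integer expansion distance in mm.
#' @param is_original if `TRUE`, the spec denotes the unmodified lesion VOI.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(inner_mm = 0L, outer_mm = 0L, is_original = FALSE) {
  inner_mm <- as.integer(inner_mm); outer_mm <- as.integer(outer_mm)
  if (is.na(inner_mm) || is.na(outer_mm) || inner_mm < 0 || outer_mm < 0)
    stop("parameter error: inner_mm and outer_mm must be nonnegative integers",
         call. = FALSE)
  if (!is_original && inner_mm == 0L && outer_mm == 0L)
    stop("the (0,0) band is empty; use is_original = TRUE for the lesion VOI",
         call. = FALSE)
  structure(list(inner_mm = inner_mm, outer_mm = outer_mm,
                 is_original = is_original), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(spec_label(x), "\n")
  invisible(x)
}

spec_label <- function(spec) {
  if (spec$is_original) "original"
  else sprintf("in%d_out%d", spec$inner_mm, spec$outer_mm)
}

#' Enumerate all margin-band specs for a millimetre sweep
#'
#' Returns every integer `(inner, outer)` pair in `[0, max_mm]^2` except
#' `(0, 0)`, plus the original-lesion spec. The order is deterministic: the
#' original spec first, then pairs sorted by `inner_mm`, then `outer_mm`.
#' With `max_mm = 10` this gives the 120 margin regions plus the original
#' VOI, i.e. 121 regions per lesion.
#'
#' @param max_mm positive integer sweep maximum in mm.
#' @param include_original include the original-lesion spec (default `TRUE`).
#' @return List of [band_spec()] objects.
#' @export
enumerate_band_specs <- function(max_mm = 10L, include_original = TRUE) {
  max_mm <- as.integer(max_mm)
  if (is.na(max_mm) || max_mm < 1L)
    stop("parameter error: max_mm must be >= 1", call. = FALSE)
  grid <- expand.grid(outer_mm = 0:max_mm, inner_mm = 0:max_mm)
  grid <- grid[order(grid$inner_mm, grid$outer_mm), ]
  grid <- grid[!(grid$inner_mm == 0 & grid$outer_mm == 0), ]
  specs <- mapply(function(i, o) band_spec(i, o), grid$inner_mm, grid$outer_mm,
                  SIMPLIFY = FALSE)
  if (include_original) specs <- c(list(band_spec(0L, 0L, TRUE)), specs)
  unname(specs)
}

#' Squared Euclidean distance transform
#'
#' Exact squared Euclidean distance (in physical units) from every voxel to
#' the nearest foreground voxel of a mask, on an isotropic grid.
#'
#' @param mask a [mask_volume()] on an isotropic grid.
#' @return Numeric 3D array of squared distances (mm^2); `Inf` if the mask
#'   is empty.
#' @export
distance_transform_sq <- function(mask) {
  if (!is_isotropic(mask))
    stop("precondition error: distance transform requires an isotropic grid",
         call. = FALSE)
  d <- dim(mask$voxels)
  out <- cpp_sedt(as.integer(mask$voxels != 0), as.integer(d))
  dim(out) <- d
  out * mask$spacing[1]^2
}

# Both distance maps needed to threshold any band out of one lesion mask:
# dist_in_sq  — squared distance of in-mask voxels to the mask complement
# dist_out_sq — squared distance of out-of-mask voxels to the mask
band_distance_maps <- function(mask) {
  inside <- mask$voxels != 0
  d_to_mask <- distance_transform_sq(mask)
  comp <- mask_volume(array(as.integer(!inside), dim(mask$voxels)),
                      mask$spacing, mask$origin)
  d_to_comp <- distance_transform_sq(comp)
  list(inside = inside, din2 = d_to_comp, dout2 = d_to_mask)
}

band_voxels_from_maps <- function(maps, spec) {
  if (spec$is_original) return(maps$inside)
  sel <- array(FALSE, dim(maps$inside))
  if (spec$inner_mm > 0)
    sel <- sel | (maps$inside & maps$din2 <= spec$inner_mm^2)
  if (spec$outer_mm > 0)
    sel <- sel | (!maps$inside & maps$dout2 <= spec$outer_mm^2)
  sel
}

#' Construct a margin-band mask
#'
#' `dilate(mask, outer_mm)` set-minus `erode(mask, inner_mm)`, both with an
#' exact Euclidean ball structuring element of the stated mm radius
#' (erosion keeps voxels whose distance to the mask complement exceeds
#' `inner_mm`; dilation adds voxels within `outer_mm` of the mask). An
#' `is_original` spec returns the mask unchanged. When erosion consumes the
#' whole lesion and `outer_mm = 0`, the returned mask is empty and carries
#' an `empty` flag.
#'
#' @param mask nonempty [mask_volume()] on an isotropic grid.
#' @param spec a [band_spec()].
#' @return A [mask_volume()] with attribute `spec`.
#' @export
make_band <- function(mask, spec) {
  if (!inherits(mask, "mask_volume")) stop("mask must be a mask_volume", call. = FALSE)
  if (sum(mask$voxels) == 0) stop("input error: empty input mask", call. = FALSE)
  if (!is_isotropic(mask))
    stop("precondition error: make_band requires an isotropic grid", call. = FALSE)
  degenerate <- FALSE
  if (spec$is_original) {
    out <- mask
  } else {
    maps <- band_distance_maps(mask)
    sel <- band_voxels_from_maps(maps, spec)
    out <- mask_volume(array(as.integer(sel), dim(mask$voxels)),
                       mask$spacing, mask$origin)
    # erosion consumed the whole lesion: with no outward expansion the band
    # degenerates to the entire lesion rather than a proper rim
    if (spec$inner_mm > 0 && spec$outer_mm == 0 &&
        !any(maps$din2[maps$inside] > spec$inner_mm^2))
      degenerate <- TRUE
  }
  attr(out, "spec") <- spec
  attr(out, "empty") <- sum(out$voxels) == 0 || degenerate
  out
}

#' Flag margin-band voxels outside an organ mask
#'
#' Counts band voxels lying outside the supplied organ (e.g. liver) label
#' mask, per nontarget label. When no organ mask is available the report is
#' marked not assessable rather than raising an error.
#'
#' @param band a band [mask_volume()].
#' @param organ_mask a [volume_grid()] of integer labels (0 = outside the
#'   organ of interest counts as nontarget label 0; any nonzero label other
#'   than `target_label` is a named nontarget tissue), or `NULL`.
#' @param target_label the organ label regarded as target tissue (default 1).
#' @return A list of class `nontarget_report` with `assessable`, `flagged`,
#'   and a `counts` data.frame (label, voxels_outside).
#' @export
nontarget_report <- function(band, organ_mask = NULL, target_label = 1L) {
  if (is.null(organ_mask)) {
    return(structure(list(assessable = FALSE, flagged = NA,
                          counts = data.frame(label = integer(),
                                              voxels_outside = integer())),
                     class = "nontarget_report"))
  }
  check_paired(organ_mask, band)
  lab <- organ_mask$voxels[band$voxels != 0]
  out <- lab[lab != target_label]
  counts <- as.data.frame(table(label = out), stringsAsFactors = FALSE)
  if (nrow(counts)) {
    counts$label <- as.integer(as.character(counts$label))
    names(counts)[2] <- "voxels_outside"
    counts$voxels_outside <- as.integer(counts$voxels_outside)
  } else {
    counts <- data.frame(label = integer(), voxels_outside = integer())
  }
  structure(list(assessable = TRUE, flagged = length(out) > 0, counts = counts),
            class = "nontarget_report")
}

#' @export
print.nontarget_report <- function(x, ...) {
  if (!x$assessable) cat("<nontarget_report> not assessable (no organ mask)\n")
  else {
    cat(sprintf("<nontarget_report> flagged: %s\n", x$flagged))
    if (nrow(x$counts)) print(x$counts, row.names = FALSE)
  }
  invisible(x)
}
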