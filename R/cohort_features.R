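# Cohort-level feature extraction: one feature table per band spec, all
# sharing patient ids, labels and cohort assignment.

#' Extract per-spec feature tables for a whole cohort
#'
#' Resamples each patient to the isotropic working grid, computes the
#' filtered volumes and lesion distance maps once per patient, then fills
#' one feature table per margin-band spec. A patient whose band is empty
#' for a spec (erosion consumed the lesion) gets NA features in that spec's
#' table only.
#'
#' @param cohort an `omr_cohort` (with images) or the result of
#'   [read_cohort()].
#' @param specs list of [band_spec()]s (default the full 121-region sweep).
#' @param registry feature names (default [omr_feature_names]).
#' @param bin_width texture discretization bin width (default 25).
#' @param target_mm isotropic working spacing in mm (default 1).
#' @param verbose print a progress line every 25 patients.
#' @return Named list of data.frames (`patient_id`, `label`, `cohort`, one
#'   column per feature), each carrying its `spec` attribute.
#' @export
extract_cohort_features <- function(cohort, specs = enumerate_band_specs(10),
                                    registry = omr_feature_names,
                                    bin_width = 25, target_mm = 1,
                                    verbose = FALSE) {
  if (is.null(cohort$patients))
    stop("input error: cohort has no images", call. = FALSE)
  tab <- cohort$table
  n <- nrow(tab)
  spec_names <- vapply(specs, spec_label, "")
  vals <- lapply(spec_names, function(s)
    matrix(NA_real_, n, length(registry), dimnames = list(NULL, registry)))
  names(vals) <- spec_names
  max_outer <- max(vapply(specs, function(s) s$outer_mm, 0L))
  # registries made only of batchable statistics take the fast path: one
  # C++ call per filtered volume covering every band at once
  batch_cols <- c(JointEntropy = 1L, ClusterShade = 2L, Imc1 = 3L, MCC = 4L,
                  Busyness = 5L, Minimum = 6L)
  for (i in seq_len(n)) {
    pt <- cohort$patients[[tab$patient_id[i]]]
    vol <- resample_isotropic(pt$volume, target_mm, "continuous")
    msk <- resample_isotropic(pt$mask, target_mm, "nearest")
    ctx <- feature_context(vol, msk, registry, bin_width,
                           max_outer_mm = max(max_outer, 1L))
    idx0 <- lapply(specs, function(sp) band_indices(ctx, sp) - 1L)
    empty <- vapply(idx0, length, 0L) == 0
    if (any(empty))
      warning("empty band(s) ", paste(spec_names[empty], collapse = ", "),
              " for patient ", tab$patient_id[i], "; marked missing")
    batchable <- vapply(ctx$parsed, function(p)
      p$class == "shape" ||
        (p$class %in% c("glcm", "ngtdm", "firstorder") &&
           p$stat %in% names(batch_cols)), TRUE)
    if (all(batchable)) {
      dims <- as.integer(dim(vol$voxels))
      keys <- unique(vapply(ctx$parsed[vapply(ctx$parsed, function(p)
        p$class != "shape", TRUE)], context_key, ""))
      per_key <- lapply(keys, function(key) {
        ps <- Filter(function(p) p$class != "shape" &&
                       context_key(p) == key, ctx$parsed)
        glcm_stats <- unlist(lapply(ps, function(p)
          if (p$class == "glcm") p$stat))
        cpp_texture_batch(ctx$vols[[key]]$voxels, dims, idx0, bin_width,
                          length(glcm_stats) > 0, "MCC" %in% glcm_stats,
                          any(vapply(ps, function(p) p$class == "ngtdm", TRUE)),
                          any(vapply(ps, function(p)
                            p$class == "firstorder", TRUE)))
      })
      names(per_key) <- keys
      for (nm in registry) {
        p <- ctx$parsed[[nm]]
        if (p$class == "shape") {
          el <- shape_elongation(msk)
          for (s in which(!empty)) vals[[s]][i, nm] <- el
        } else {
          col <- batch_cols[[p$stat]]
          v <- per_key[[context_key(p)]][, col]
          for (s in which(!empty)) vals[[s]][i, nm] <- v[s]
        }
      }
    } else {
      for (s in which(!empty))
        vals[[s]][i, ] <- extract_from_context(ctx, idx0[[s]])
    }
    if (verbose && i %% 25 == 0)
      message("  extracted ", i, "/", n, " patients")
  }
  out <- lapply(seq_along(specs), function(s) {
    df <- data.frame(patient_id = tab$patient_id, label = tab$label,
                     cohort = tab$cohort, vals[[s]],
                     stringsAsFactors = FALSE, check.names = FALSE)
    attr(df, "spec") <- specs[[s]]
    df
  })
  names(out) <- spec_names
  out
}

#' Nontarget-tissue flags across a cohort and band sweep
#'
#' For every patient and spec, counts band voxels outside the organ mask
#' per nontarget label. At a fixed inner erosion, the flagged-patient count
#' is nondecreasing in the outer expansion (dilation monotonicity).
#'
#' @inheritParams extract_cohort_features
#' @return Data.frame with `patient_id`, `inner_mm`, `outer_mm`, `label`,
#'   `voxels_outside`, plus rows with label NA and 0 voxels for assessable,
#'   unflagged patient-specs; patients without an organ mask are omitted.
#' @export
nontarget_cohort_report <- function(cohort, specs = enumerate_band_specs(10),
                                    target_mm = 1) {
  tab <- cohort$table
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    pt <- cohort$patients[[tab$patient_id[i]]]
    if (is.null(pt$organ)) next
    msk <- resample_isotropic(pt$mask, target_mm, "nearest")
    org <- resample_isotropic(pt$organ, target_mm, "nearest")
    maps <- band_distance_maps(msk)
    for (spec in specs) {
      sel <- band_voxels_from_maps(maps, spec)
      band <- mask_volume(array(as.integer(sel), dim(msk$voxels)),
                          msk$spacing, msk$origin)
      nr <- nontarget_report(band, org)
      base <- data.frame(patient_id = tab$patient_id[i],
                         inner_mm = spec$inner_mm, outer_mm = spec$outer_mm,
                         stringsAsFactors = FALSE)
      if (nrow(nr$counts)) {
        rows[[length(rows) + 1L]] <- cbind(base[rep(1, nrow(nr$counts)), ],
                                           nr$counts)
      } else {
        rows[[length(rows) + 1L]] <- cbind(base, data.frame(
          label = NA_integer_, voxels_outside = 0L))
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(patient_id = character(), inner_mm = integer(),
                      outer_mm = integer(), label = integer(),
                      voxels_outside = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Persist per-spec feature tables as one long CSV
#'
#' One row per patient and band spec, with a header comment carrying a
#' hash of the extraction configuration so stale tables are detectable.
#'
#' @param features_by_spec result of [extract_cohort_features()].
#' @param path output CSV path.
#' @param config optional list describing the extraction configuration.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features_by_spec, path, config = list()) {
  rows <- lapply(names(features_by_spec), function(nm) {
    df <- features_by_spec[[nm]]
    sp <- attr(df, "spec")
    cbind(data.frame(spec = nm, inner_mm = sp$inner_mm,
                     outer_mm = sp$outer_mm, is_original = sp$is_original),
          df)
  })
  out <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  cfg_json <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE)
  writeLines(sprintf("# omrad features, config %s", fnv1a(as.character(cfg_json))), con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}
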