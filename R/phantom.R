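# Deterministic phantom-cohort simulator. The phantoms emulate
# hepatobiliary-phase-like volumes: a bright smooth liver background, a
# darker ellipsoidal lesion, and a margin rim (the planted band) whose
# voxel-noise SD is coupled to the binary label. The planted effect is a
# variance (texture-heterogeneity) difference, not a mean shift, so it is
# visible to texture features but not to trivial first-order means.

#' Default phantom-cohort parameters
#'
#' The study conditions of the simulator: 1 mm isotropic grid; lesion
#' semi-axes uniform on 11-15 mm (solitary tumors just over 2 cm); liver
#' background mean 120 / SD 10 with a smooth spatial component; lesion mean
#' 80 / SD 10; planted band = inner 5 mm, outer 0 mm rim with the label-1
#' noise SD multiplied by `effect_size` (default 2); label prevalence 0.4;
#' survival exponential with class hazard ratio 3 (median 60 months
#' overall survival and 40 months disease-free survival in the label-0
#' class) under independent uniform censoring on 12-84 months; 70/30
#' train/internal-test split.
#'
#' @return Named list of parameters accepted by [generate_cohort()].
#' @export
phantom_defaults <- function() {
  list(
    spacing = 1,
    semi_axes = c(11, 15),
    margin_mm = 10,
    background_mean = 120, background_sd = 10,
    lesion_mean = 80, lesion_sd = 10,
    planted = band_spec(5L, 0L),
    effect_size = 2,
    texture_var_sd = 0.2,
    core_var_sd = 0.35, parenchyma_var_sd = 0.7,
    prevalence = 0.4,
    hazard_ratio = 3,
    os_median_months = 60, dfs_median_months = 40,
    censor_range = c(12, 84),
    cavity_fraction = 0, cavity_radius_mm = 6,
    train_frac = 0.7, external_frac = 0
  )
}

# trilinear upsampling of a coarse noise grid: cheap smooth texture
smooth_noise <- function(dims, coarse = 4) {
  cd <- pmax(2L, as.integer(ceiling(dims / coarse)) + 1L)
  g <- array(stats::rnorm(prod(cd)), cd)
  vg <- volume_grid(g, spacing = rep(coarse, 3))
  up <- resample_isotropic(vg, 1, mode = "continuous")$voxels
  out <- array(0, dims)
  d <- pmin(dim(up), dims)
  out[1:d[1], 1:d[2], 1:d[3]] <- up[1:d[1], 1:d[2], 1:d[3]]
  out
}

generate_patient <- function(params, label, seed) {
  with_local_seed(seed, {
    semi <- stats::runif(3, params$semi_axes[1], params$semi_axes[2])
    half <- ceiling(max(semi) + params$margin_mm + 3)
    n <- as.integer(2 * half + 1)
    dims <- c(n, n, n)
    ctr <- half  # 0-based center index
    ax <- (0:(n - 1)) - ctr
    e1 <- (ax / semi[1])^2; e2 <- (ax / semi[2])^2; e3 <- (ax / semi[3])^2
    inside <- outer(outer(e1, e2, "+"), e3, "+") <= 1
    mask <- mask_volume(array(as.integer(inside), dims))

    # per-patient texture scales: scanners, parenchyma and tumor cores vary
    # from patient to patient independently of the label. Without the
    # global scale `u` texture features would separate the classes
    # perfectly; the core and parenchyma scales are label-free nuisance
    # heterogeneity, so volumes of interest reaching beyond the margin zone
    # pick up patient-random variation that dilutes the label signal.
    u <- exp(stats::rnorm(1, 0, params$texture_var_sd))
    u_core <- exp(stats::rnorm(1, 0, params$core_var_sd))
    u_par <- exp(stats::rnorm(1, 0, params$parenchyma_var_sd))

    bg_smooth <- smooth_noise(dims) * (params$background_sd * 0.7 * u_par)
    vox <- params$background_mean + bg_smooth +
      stats::rnorm(prod(dims), sd = params$background_sd * 0.7 * u_par)
    dim(vox) <- dims
    les_sel <- which(inside)
    vox[les_sel] <- params$lesion_mean +
      stats::rnorm(length(les_sel), sd = params$lesion_sd * u * u_core)

    # label-coupled heterogeneity in the planted band: the noise variance
    # ramps linearly with distance from the lesion surface, reaching
    # effect_size^2-fold at the band's deep edge, so the full band (not any
    # thin sub-shell of it) is the most informative region
    maps <- band_distance_maps(mask)
    rim <- which(band_voxels_from_maps(maps, params$planted))
    depth <- numeric(length(rim))
    rim_inside <- inside[rim]
    if (params$planted$inner_mm > 0)
      depth[rim_inside] <- sqrt(maps$din2[rim[rim_inside]]) /
        params$planted$inner_mm
    if (params$planted$outer_mm > 0)
      depth[!rim_inside] <- sqrt(maps$dout2[rim[!rim_inside]]) /
        params$planted$outer_mm
    w <- pmin(depth, 1)
    gain2 <- if (label == 1) 1 + (params$effect_size^2 - 1) * w else rep(1, length(rim))
    rim_mean <- ifelse(rim_inside, params$lesion_mean, params$background_mean)
    vox[rim] <- rim_mean +
      stats::rnorm(length(rim), sd = params$lesion_sd * u * sqrt(gain2))

    organ <- NULL
    if (stats::runif(1) < params$cavity_fraction) {
      r <- params$cavity_radius_mm
      # adjacent along +x: the cavity surface sits 1 mm off the lesion
      # surface, so it never carves into the tumor but outward expansions
      # beyond 1 mm reach it
      cx <- ctr + semi[1] + r + 1
      dist2 <- outer(outer((ax - (cx - ctr))^2, ax^2, "+"), ax^2, "+")
      cav <- dist2 <= r^2
      vox[cav] <- 0
      lab <- array(1L, dims)
      lab[cav] <- 2L
      organ <- volume_grid(lab, rep(params$spacing, 3))
    }
    list(volume = volume_grid(vox, rep(params$spacing, 3)),
         mask = mask, organ = organ, semi_axes = semi)
  })
}

#' Generate a deterministic phantom cohort
#'
#' Simulates `n` patients with [phantom_defaults()] conditions (overridable
#' through `params`): label-coupled rim texture, label-coupled exponential
#' survival with uniform censoring, and a recorded train/internal-test
#' split. The same seed always yields a bit-identical cohort.
#'
#' @param n number of patients (>= 20).
#' @param seed master integer seed.
#' @param params named list overriding entries of [phantom_defaults()].
#' @param images generate image volumes (`TRUE`) or only labels, survival
#'   and cohort assignment (`FALSE`, for tabular-only work).
#' @return An object of class `omr_cohort`: `patients` (per patient:
#'   `volume`, `mask`, optional `organ`), `table` (patient_id, label,
#'   cohort, time, event, dfs_time, dfs_event), `truth` (parameters, seed,
#'   planted spec).
#' @export
generate_cohort <- function(n, seed = 1L, params = list(), images = TRUE) {
  if (n < 20) stop("input error: n must be >= 20", call. = FALSE)
  p <- utils::modifyList(phantom_defaults(), params)
  if (p$semi_axes[1] < 8)
    stop("geometry error: semi-axes must be >= 8 mm so the 5 mm inner rim exists",
         call. = FALSE)
  labels <- with_local_seed(derive_seed(seed, "labels"),
                            stats::rbinom(n, 1, p$prevalence))
  if (length(unique(labels)) < 2) {  # tiny cohorts: force both classes
    labels[1] <- 0L; labels[2] <- 1L
  }
  surv <- with_local_seed(derive_seed(seed, "survival"), {
    rate_os <- log(2) / p$os_median_months
    rate_dfs <- log(2) / p$dfs_median_months
    hr <- ifelse(labels == 1, p$hazard_ratio, 1)
    t_os <- stats::rexp(n, rate_os * hr)
    t_dfs <- stats::rexp(n, rate_dfs * hr)
    cens <- stats::runif(n, p$censor_range[1], p$censor_range[2])
    cens_dfs <- stats::runif(n, p$censor_range[1], p$censor_range[2])
    data.frame(time = pmin(t_os, cens), event = as.integer(t_os <= cens),
               dfs_time = pmin(t_dfs, cens_dfs),
               dfs_event = as.integer(t_dfs <= cens_dfs))
  })
  cohort <- with_local_seed(derive_seed(seed, "split"), {
    ch <- rep("training", n)
    n_ext <- round(p$external_frac * n)
    n_int <- round((1 - p$train_frac) * (n - n_ext))
    idx <- sample(n)
    ch[idx[seq_len(n_int)]] <- "internal_test"
    if (n_ext > 0) ch[idx[n_int + seq_len(n_ext)]] <- "external_test"
    ch
  })
  patients <- NULL
  if (images) {
    patients <- lapply(seq_len(n), function(i)
      generate_patient(p, labels[i], derive_seed(seed, "patient", i)))
    names(patients) <- sprintf("P%03d", seq_len(n))
  }
  tab <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                    label = labels, cohort = cohort, surv,
                    stringsAsFactors = FALSE)
  structure(list(patients = patients, table = tab,
                 truth = list(params = p, seed = seed, planted = p$planted)),
            class = "omr_cohort")
}

#' @export
print.omr_cohort <- function(x, ...) {
  cat(sprintf("<omr_cohort> %d patients (%s images), planted band %s, effect %.2g\n",
              nrow(x$table), if (is.null(x$patients)) "no" else "with",
              spec_label(x$truth$planted), x$truth$params$effect_size))
  print(table(x$table$cohort, x$table$label))
  invisible(x)
}

#' Write a phantom cohort to a ready-to-run directory
#'
#' NIfTI volumes and masks, a `patients.csv` table, and a `truth.json`
#' record of the generating parameters.
#'
#' @param cohort an `omr_cohort` with images.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (is.null(cohort$patients))
    stop("input error: cohort has no images", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- cohort$table
  tab$image_path <- file.path(dir, paste0(tab$patient_id, "_img.nii.gz"))
  tab$mask_path <- file.path(dir, paste0(tab$patient_id, "_mask.nii.gz"))
  for (i in seq_len(nrow(tab))) {
    pt <- cohort$patients[[tab$patient_id[i]]]
    write_volume(pt$volume, tab$image_path[i])
    write_volume(pt$mask, tab$mask_path[i])
    if (!is.null(pt$organ)) {
      lp <- file.path(dir, paste0(tab$patient_id, "_liver.nii.gz"))
      write_volume(pt$organ, lp)
      tab$liver_mask_path[i] <- lp
    }
  }
  utils::write.csv(tab, file.path(dir, "patients.csv"), row.names = FALSE)
  truth <- cohort$truth
  truth$params$planted <- unclass(truth$params$planted)
  truth$planted <- unclass(truth$planted)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a cohort directory
#'
#' Expects a `patients.csv` with columns `patient_id`, `image_path`,
#' `mask_path`, `label`, and optional `time`, `event`, `dfs_time`,
#' `dfs_event`, `cohort`, `liver_mask_path`.
#'
#' @param dir cohort directory.
#' @return An `omr_cohort`.
#' @export
read_cohort <- function(dir) {
  csv <- file.path(dir, "patients.csv")
  if (!file.exists(csv))
    stop("input error: no patients.csv in ", dir, call. = FALSE)
  tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
  need <- c("patient_id", "image_path", "mask_path", "label")
  if (!all(need %in% names(tab)))
    stop("input error: patients.csv must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0) stop("input error: cohort has zero patients", call. = FALSE)
  if (is.null(tab$cohort)) tab$cohort <- "training"
  patients <- lapply(seq_len(nrow(tab)), function(i) {
    out <- list(volume = read_volume(tab$image_path[i]),
                mask = read_mask(tab$mask_path[i]))
    if (!is.null(tab$liver_mask_path) && !is.na(tab$liver_mask_path[i]) &&
        nzchar(tab$liver_mask_path[i]))
      out$organ <- read_volume(tab$liver_mask_path[i])
    out
  })
  names(patients) <- tab$patient_id
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  structure(list(patients = patients, table = tab, truth = truth),
            class = "omr_cohort")
}

#' Recovery report for a planted margin band
#'
#' Compares an [omr_search()] ranking against the generating truth of a
#' phantom cohort: the Manhattan distance `|d inner| + |d outer|` between
#' the top-ranked spec and the planted spec, the best rank the planted spec
#' itself achieved, and whether the top spec is within `tol` of truth.
#'
#' @param search an `omr_search`.
#' @param truth an `omr_cohort$truth` record (or a [band_spec()]).
#' @param tol Manhattan-distance recovery tolerance (default 2).
#' @return List with `top_spec`, `distance`, `planted_rank`, `recovered`.
#' @export
truth_check <- function(search, truth, tol = 2) {
  planted <- if (inherits(truth, "band_spec")) truth else truth$planted
  res <- search$results
  top <- res[1, ]
  dist <- if (top$is_original) NA_integer_ else
    abs(top$inner_mm - planted$inner_mm) + abs(top$outer_mm - planted$outer_mm)
  pl_rows <- res$inner_mm == planted$inner_mm &
    res$outer_mm == planted$outer_mm & !res$is_original
  planted_rank <- if (any(pl_rows)) min(res$rank[pl_rows]) else NA_integer_
  list(top_spec = sprintf("in%d_out%d", top$inner_mm, top$outer_mm),
       distance = dist, planted_rank = planted_rank,
       recovered = !is.na(dist) && dist <= tol)
}
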