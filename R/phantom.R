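#' Specify a focal uptake source inside a phantom nodule
#'
#' A focus is a 3-D Gaussian activity source. Its in-plane centre may drift
#' from slice to slice, emulating the apparent displacement of the
#' maximum-uptake locus seen in heterogeneous (malignant-like) nodules;
#' a zero drift gives the stable focus typical of benign-like nodules.
#'
#' @param amplitude Peak activity above background (arbitrary activity
#'   units, > 0).
#' @param sigma_mm Gaussian standard deviation in mm (> 0), applied
#'   isotropically in 3-D.
#' @param center_mm Numeric length-3 centre in mm, ordered like the volume
#'   axes: (axial, row, column).
#' @param drift_mm_per_slice Numeric length-2 in-plane displacement
#'   (row, column) of the focus centre per slice, in mm.
#' @return A `focus_spec` list.
#' @export
focus_spec <- function(amplitude, sigma_mm, center_mm,
                       drift_mm_per_slice = c(0, 0)) {
  stopifnot_scalar_number(amplitude, "amplitude", positive = TRUE)
  stopifnot_scalar_number(sigma_mm, "sigma_mm", positive = TRUE)
  if (!is.numeric(center_mm) || length(center_mm) != 3L) {
    abort("`center_mm` must be a numeric vector of length 3 (axial, row, col).")
  }
  if (!is.numeric(drift_mm_per_slice) || length(drift_mm_per_slice) != 2L) {
    abort("`drift_mm_per_slice` must be a numeric vector of length 2.")
  }
  structure(
    list(amplitude = amplitude, sigma_mm = sigma_mm,
         center_mm = as.numeric(center_mm),
         drift_mm_per_slice = as.numeric(drift_mm_per_slice)),
    class = "focus_spec"
  )
}

#' Specify a synthetic PET phantom
#'
#' Describes a rectangular activity volume holding a single pulmonary
#' nodule: uniform lung background, one or more Gaussian uptake foci, and
#' additive Gaussian noise clipped at zero. The nodule diameter must lie in
#' 10--30 mm, the working definition of a solitary pulmonary nodule at PET
#' resolution.
#'
#' An optional `reference` structure -- a hot in-plane Gaussian column
#' spanning all slices, placed away from the nodule -- stands in for the
#' mediastinal blood pool. It anchors the dynamic range of every slice so
#' that per-slice min-max normalisation leaves the nodule peak at an
#' intermediate gray band (as in real thoracic slices, where the nodule is
#' rarely the hottest structure in the field of view).
#'
#' @param grid_shape Integer length-3 voxel counts (slices, rows, cols).
#' @param in_plane_spacing_mm Pixel spacing in mm (> 0).
#' @param slice_thickness_mm Slice thickness in mm (> 0, default 3.3).
#' @param background_activity Uniform background level (>= 0).
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#' @param nodule_center_mm Numeric length-3 nodule centre in mm
#'   (axial, row, col).
#' @param nodule_radius_mm Nodule radius in mm, within \[5, 15\].
#' @param foci List of [focus_spec()] objects; every focus centre must lie
#'   within `nodule_radius_mm` of the nodule centre.
#' @param seed Integer RNG seed; the phantom is fully deterministic given
#'   the spec.
#' @param suvmax Target SUV of the hottest voxel of the noise-free volume;
#'   used to fix the SUV calibration of the generated series. Default 5.
#' @param reference Optional list with elements `amplitude`, `sigma_mm`,
#'   `center_rc_mm` (length-2, row/col mm) describing the reference column,
#'   or `NULL` for none.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape,
                         in_plane_spacing_mm,
                         slice_thickness_mm = 3.3,
                         background_activity = 0,
                         noise_sd = 0,
                         nodule_center_mm,
                         nodule_radius_mm,
                         foci = list(),
                         seed = 1L,
                         suvmax = 5,
                         reference = NULL) {
  if (!is.numeric(grid_shape) || length(grid_shape) != 3L ||
      any(grid_shape < 1)) {
    abort("`grid_shape` must be three positive voxel counts (slices, rows, cols).")
  }
  stopifnot_scalar_number(in_plane_spacing_mm, "in_plane_spacing_mm",
                          positive = TRUE)
  stopifnot_scalar_number(slice_thickness_mm, "slice_thickness_mm",
                          positive = TRUE)
  stopifnot_scalar_number(background_activity, "background_activity",
                          nonnegative = TRUE)
  stopifnot_scalar_number(noise_sd, "noise_sd", nonnegative = TRUE)
  stopifnot_scalar_number(nodule_radius_mm, "nodule_radius_mm")
  if (nodule_radius_mm < 5 || nodule_radius_mm > 15) {
    abort("`nodule_radius_mm` must lie in [5, 15] mm (nodule diameter 10-30 mm).")
  }
  if (!is.numeric(nodule_center_mm) || length(nodule_center_mm) != 3L) {
    abort("`nodule_center_mm` must be a numeric vector of length 3.")
  }
  foci <- lapply(foci, function(f) {
    if (!inherits(f, "focus_spec")) abort("`foci` must be a list of focus_spec objects.")
    d <- sqrt(sum((f$center_mm - nodule_center_mm)^2))
    if (d > nodule_radius_mm + 1e-9) {
      abort(sprintf(
        "focus centre %.1f mm from nodule centre exceeds nodule radius %.1f mm",
        d, nodule_radius_mm))
    }
    f
  })
  if (!is.null(reference)) {
    stopifnot_scalar_number(reference$amplitude, "reference$amplitude",
                            positive = TRUE)
    stopifnot_scalar_number(reference$sigma_mm, "reference$sigma_mm",
                            positive = TRUE)
    if (length(reference$center_rc_mm) != 2L) {
      abort("`reference$center_rc_mm` must be a numeric vector of length 2.")
    }
  }
  structure(
    list(grid_shape = as.integer(grid_shape),
         in_plane_spacing_mm = in_plane_spacing_mm,
         slice_thickness_mm = slice_thickness_mm,
         background_activity = background_activity,
         noise_sd = noise_sd,
         nodule_center_mm = as.numeric(nodule_center_mm),
         nodule_radius_mm = nodule_radius_mm,
         foci = foci,
         seed = as.integer(seed),
         suvmax = suvmax,
         reference = reference),
    class = "phantom_spec"
  )
}

#' Construct a PET series object
#'
#' The in-memory container for an ordered stack of axial PET slices. Values
#' in `activity` are activity concentrations in the unit convention of the
#' SUV formula (mCi/kg by default), so that
#' `suv(activity, injected_activity_mCi, body_weight_kg)` is dimensionless.
#'
#' @param activity 3-D numeric array (slice, row, col), nonnegative.
#' @param in_plane_spacing_mm,slice_thickness_mm Voxel geometry in mm.
#' @param injected_activity_mCi Injected tracer activity (mCi) or `NA`.
#' @param body_weight_kg Patient body weight (kg) or `NA`.
#' @param meta Named list of opaque acquisition metadata.
#' @return A `pet_series` object.
#' @export
pet_series <- function(activity, in_plane_spacing_mm, slice_thickness_mm,
                       injected_activity_mCi = NA_real_,
                       body_weight_kg = NA_real_, meta = list()) {
  if (!is.array(activity) || length(dim(activity)) != 3L) {
    abort("`activity` must be a 3-D array (slice, row, col).")
  }
  if (any(activity < 0)) abort("`activity` must be nonnegative.")
  structure(
    list(activity = activity,
         in_plane_spacing_mm = in_plane_spacing_mm,
         slice_thickness_mm = slice_thickness_mm,
         injected_activity_mCi = injected_activity_mCi,
         body_weight_kg = body_weight_kg,
         meta = meta),
    class = "pet_series"
  )
}

#' @export
print.pet_series <- function(x, ...) {
  d <- dim(x$activity)
  cat(sprintf(
    "<pet_series> %d slices of %dx%d, %.4g mm in-plane, %.3g mm thick\n",
    d[1], d[2], d[3], x$in_plane_spacing_mm, x$slice_thickness_mm))
  cat(sprintf("  activity range [%.4g, %.4g]", min(x$activity), max(x$activity)))
  if (is.finite(x$injected_activity_mCi) && is.finite(x$body_weight_kg)) {
    cat(sprintf(", SUVmax %.2f",
                max(x$activity) * x$body_weight_kg / x$injected_activity_mCi))
  }
  cat("\n")
  invisible(x)
}

# noise-free activity volume for a phantom spec (background + foci [+ reference])
phantom_field <- function(spec) {
  d <- spec$grid_shape
  sp <- spec$in_plane_spacing_mm
  th <- spec$slice_thickness_mm
  row_mm <- index_to_mm(seq_len(d[2]), sp)
  col_mm <- index_to_mm(seq_len(d[3]), sp)
  vol <- array(spec$background_activity, dim = d)
  plane <- matrix(0, d[2], d[3])
  if (!is.null(spec$reference)) {
    r <- spec$reference
    d2 <- outer((row_mm - r$center_rc_mm[1])^2, (col_mm - r$center_rc_mm[2])^2, `+`)
    plane <- r$amplitude * exp(-d2 / (2 * r$sigma_mm^2))
  }
  for (s in seq_len(d[1])) {
    z <- index_to_mm(s, th)
    sl <- plane
    for (f in spec$foci) {
      s0 <- mm_to_index(f$center_mm[1], th)
      ctr <- f$center_mm[2:3] + f$drift_mm_per_slice * (s - s0)
      dz2 <- (z - f$center_mm[1])^2
      d2 <- outer((row_mm - ctr[1])^2, (col_mm - ctr[2])^2, `+`) + dz2
      sl <- sl + f$amplitude * exp(-d2 / (2 * f$sigma_mm^2))
    }
    vol[s, , ] <- vol[s, , ] + sl
  }
  vol
}

#' Generate a synthetic PET series from a phantom spec
#'
#' Voxel value = background + sum of focus Gaussians (+ reference column)
#' + Gaussian noise, clipped at zero. Voxel values stay in the spec's
#' activity units; the SUV calibration constants (body weight 70 kg and a
#' matching injected activity) are chosen so that the hottest noise-free
#' voxel maps to `spec$suvmax`. Fully deterministic given the spec (the
#' seed lives in the spec).
#'
#' @param spec A [phantom_spec()].
#' @return A [pet_series()] with `meta$phantom_spec` attached.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) abort("`spec` must be a phantom_spec.")
  vol <- phantom_field(spec)
  peak <- max(vol)
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       array(rnorm(length(vol), sd = spec$noise_sd), dim = dim(vol)))
    vol <- vol + noise
  }
  vol[vol < 0] <- 0
  weight <- 70
  injected <- if (peak > 0) peak * weight / spec$suvmax else 10
  pet_series(vol,
             in_plane_spacing_mm = spec$in_plane_spacing_mm,
             slice_thickness_mm = spec$slice_thickness_mm,
             injected_activity_mCi = injected,
             body_weight_kg = weight,
             meta = list(phantom_spec = spec))
}

#' Frozen generation regimes for synthetic cohorts
#'
#' Reads the versioned regime configuration shipped with the package
#' (`inst/extdata/cohort_regimes.json`). Malignant-like nodules are drawn
#' from a high-heterogeneity regime (several uptake foci stacked at three
#' or more amplitude levels, each drifting in-plane across slices);
#' benign-like nodules from a low-heterogeneity regime (a single stable
#' focus). The file also fixes grid geometry, background, noise, and the
#' reference column shared by both regimes.
#'
#' @param path Optional path to an alternative regime JSON file.
#' @return Nested list of regime parameters.
#' @export
cohort_regimes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cohort_regimes.json", package = "petcontour")
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# draw one phantom_spec from a named regime; assumes RNG state already fixed
draw_phantom_spec <- function(regimes, which, seed) {
  rg <- regimes[[which]]
  d <- regimes$grid_shape
  sp <- regimes$in_plane_spacing_mm
  th <- regimes$slice_thickness_mm
  extent <- c(d[1] * th, d[2] * sp, d[3] * sp)
  center <- extent / 2 + c(0, runif(2, -4, 4))
  radius <- runif(1, rg$radius_mm[1], rg$radius_mm[2])
  n_foci <- if (rg$n_foci[1] == rg$n_foci[2]) rg$n_foci[1] else
    sample(rg$n_foci[1]:rg$n_foci[2], 1)
  amp1 <- runif(1, rg$primary_amplitude[1], rg$primary_amplitude[2])
  amps <- amp1
  if (n_foci > 1) {
    # stacked amplitude levels: each extra focus a fixed fraction band lower
    fr <- runif(n_foci - 1, rg$stack_fraction[1], rg$stack_fraction[2])
    amps <- c(amp1, amp1 * sort(fr, decreasing = TRUE))
  }
  foci <- vector("list", n_foci)
  for (i in seq_len(n_foci)) {
    off_r <- runif(1, rg$offset_frac[1], rg$offset_frac[2]) * radius
    ang <- runif(1, 0, 2 * pi)
    off <- c(runif(1, -0.25, 0.25) * radius, off_r * sin(ang), off_r * cos(ang))
    if (i == 1) off <- c(0, 0, 0)  # primary focus anchors the nodule centre
    mag <- runif(1, rg$drift_mag_mm[1], rg$drift_mag_mm[2])
    dir <- runif(1, 0, 2 * pi)
    foci[[i]] <- focus_spec(
      amplitude = amps[i],
      sigma_mm = runif(1, rg$sigma_mm[1], rg$sigma_mm[2]),
      center_mm = center + off,
      drift_mm_per_slice = mag * c(sin(dir), cos(dir)))
  }
  ref <- regimes$reference
  phantom_spec(
    grid_shape = d,
    in_plane_spacing_mm = sp,
    slice_thickness_mm = th,
    background_activity = regimes$background_activity,
    noise_sd = regimes$noise_sd,
    nodule_center_mm = center,
    nodule_radius_mm = radius,
    foci = foci,
    seed = seed,
    suvmax = regimes$suvmax_reference,
    reference = list(amplitude = ref$amplitude, sigma_mm = ref$sigma_mm,
                     center_rc_mm = c(ref$row_frac * extent[2],
                                      ref$col_frac * extent[3])))
}

#' Generate a labelled cohort of synthetic nodule series
#'
#' Draws `n_malignant_like` phantoms from the high-heterogeneity regime and
#' `n_benign_like` from the low-heterogeneity regime (see
#' [cohort_regimes()]), in that order. Reproducible: the same `seed` yields
#' byte-identical voxel data.
#'
#' @param n_malignant_like,n_benign_like Nonnegative counts.
#' @param seed Integer master seed.
#' @param regimes Regime list, default [cohort_regimes()].
#' @return List with `series` (list of [pet_series()]) and `manifest`
#'   (tibble: nodule_id, label, and the nodule VOI box in 1-based voxel
#'   indices, inclusive).
#' @export
generate_cohort <- function(n_malignant_like, n_benign_like, seed = 1L,
                            regimes = cohort_regimes()) {
  if (n_malignant_like < 0 || n_benign_like < 0) abort("counts must be >= 0")
  n <- n_malignant_like + n_benign_like
  labels <- rep(c("malignant", "benign"), c(n_malignant_like, n_benign_like))
  if (n == 0) {
    return(list(series = list(),
                manifest = tibble::tibble(nodule_id = character(),
                                          label = character())))
  }
  specs <- with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      draw_phantom_spec(regimes,
                        if (labels[i] == "malignant") "malignant" else "benign",
                        seed = sub_seeds[i])
    })
  })
  series <- lapply(specs, generate_phantom)
  manifest <- purrr::imap_dfr(specs, function(sp, i) {
    v <- phantom_voi(sp)
    tibble::tibble(
      nodule_id = sprintf("n%03d", i),
      label = labels[[i]],
      slice_min = v$slice_range[1], slice_max = v$slice_range[2],
      row_min = v$row_range[1], row_max = v$row_range[2],
      col_min = v$col_range[1], col_max = v$col_range[2],
      nodule_radius_mm = sp$nodule_radius_mm)
  })
  list(series = series, manifest = manifest)
}

#' Volume of interest implied by a phantom spec
#'
#' The nodule bounding box (centre +/- radius, padded) in voxel indices --
#' the synthetic analogue of the manually drawn VOI box of the clinical
#' workflow.
#'
#' @param spec A [phantom_spec()].
#' @param pad_mm Padding margin in mm (default 5).
#' @return A `pet_voi` object (see [find_voi()]).
#' @export
phantom_voi <- function(spec, pad_mm = 5) {
  d <- spec$grid_shape
  ctr <- spec$nodule_center_mm
  r <- spec$nodule_radius_mm + pad_mm
  clamp <- function(x, n) pmin(pmax(x, 1L), n)
  s_rng <- clamp(round(mm_to_index(c(ctr[1] - r, ctr[1] + r),
                                   spec$slice_thickness_mm)), d[1])
  r_rng <- clamp(round(mm_to_index(c(ctr[2] - r, ctr[2] + r),
                                   spec$in_plane_spacing_mm)), d[2])
  c_rng <- clamp(round(mm_to_index(c(ctr[3] - r, ctr[3] + r),
                                   spec$in_plane_spacing_mm)), d[3])
  seed_vox <- clamp(round(mm_to_index(ctr, c(spec$slice_thickness_mm,
                                             spec$in_plane_spacing_mm,
                                             spec$in_plane_spacing_mm))), d)
  new_voi(as.integer(s_rng), as.integer(r_rng), as.integer(c_rng),
          as.integer(seed_vox))
}
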