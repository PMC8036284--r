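#' Standardised uptake value
#'
#' `SUV = concentration * body_weight / injected_activity`, the
#' weight-normalised uptake ratio. With concentration in mCi/kg, injected
#' activity in mCi and weight in kg, the result is dimensionless. Linear in
#' concentration and inversely linear in injected activity.
#'
#' @param concentration Activity concentration (mCi/kg), nonnegative.
#' @param injected_activity_mCi Injected activity (mCi), > 0.
#' @param body_weight_kg Body weight (kg), > 0.
#' @return SUV, same shape as `concentration`.
#' @export
suv <- function(concentration, injected_activity_mCi, body_weight_kg) {
  stopifnot_scalar_number(injected_activity_mCi, "injected_activity_mCi",
                          positive = TRUE)
  stopifnot_scalar_number(body_weight_kg, "body_weight_kg", positive = TRUE)
  concentration * body_weight_kg / injected_activity_mCi
}

#' SUV volume of a PET series
#'
#' @param series A [pet_series()] with calibration fields present.
#' @return 3-D array of SUVs, same shape as the activity volume.
#' @export
suv_volume <- function(series) {
  if (!is.finite(series$injected_activity_mCi) ||
      !is.finite(series$body_weight_kg)) {
    abort("SUV unavailable: series lacks injected dose and/or patient weight.")
  }
  suv(series$activity, series$injected_activity_mCi, series$body_weight_kg)
}

new_voi <- function(slice_range, row_range, col_range, seed_voxel) {
  structure(list(slice_range = slice_range, row_range = row_range,
                 col_range = col_range, seed_voxel = seed_voxel),
            class = "pet_voi")
}

#' @export
print.pet_voi <- function(x, ...) {
  cat(sprintf("<pet_voi> slices %d-%d, rows %d-%d, cols %d-%d (seed voxel %s)\n",
              x$slice_range[1], x$slice_range[2], x$row_range[1], x$row_range[2],
              x$col_range[1], x$col_range[2],
              paste(x$seed_voxel, collapse = ",")))
  invisible(x)
}

# 26-connectivity connected component of `mask` containing `seed` (3-D BFS)
component_3d <- function(mask, seed) {
  d <- dim(mask)
  visited <- array(FALSE, dim = d)
  if (!mask[seed[1], seed[2], seed[3]]) return(visited)
  queue <- matrix(seed, ncol = 3)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  while (nrow(queue) > 0) {
    cur <- queue[nrow(queue), , drop = FALSE]
    queue <- queue[-nrow(queue), , drop = FALSE]
    nb <- sweep(offs, 2, cur[1, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    for (i in seq_len(nrow(nb))) {
      p <- nb[i, ]
      if (mask[p[1], p[2], p[3]] && !visited[p[1], p[2], p[3]]) {
        visited[p[1], p[2], p[3]] <- TRUE
        queue <- rbind(queue, p)
      }
    }
  }
  visited
}

#' Locate the hypermetabolic volume of interest
#'
#' Seeds at the global SUV maximum and grows the 26-connected component of
#' voxels with `SUV >= suv_threshold` containing it; the VOI is that
#' component's bounding box padded by `pad_mm`. A series whose SUVmax falls
#' below the threshold is not a hypermetabolic nodule and is rejected with
#' an error (out of the method's scope).
#'
#' @param series A [pet_series()] with SUV calibration.
#' @param suv_threshold Inclusion threshold for the hypermetabolic
#'   component; default 2.5, the conventional malignancy-risk cut-off.
#' @param pad_mm Padding margin added to the bounding box, in mm.
#' @return A `pet_voi`: 1-based inclusive index ranges plus the seed voxel.
#' @export
find_voi <- function(series, suv_threshold = 2.5, pad_mm = 5) {
  sv <- suv_volume(series)
  mx <- max(sv)
  if (mx < suv_threshold) {
    abort(sprintf(
      "SUVmax %.2f is below the hypermetabolic threshold %.2f; nodule out of scope",
      mx, suv_threshold))
  }
  seed <- arrayInd(which.max(sv), dim(sv))[1, ]
  comp <- component_3d(sv >= suv_threshold, seed)
  idx <- which(comp, arr.ind = TRUE)
  pad_vox <- c(ceiling(pad_mm / series$slice_thickness_mm),
               rep(ceiling(pad_mm / series$in_plane_spacing_mm), 2))
  d <- dim(sv)
  rng <- function(ax) {
    lo <- max(1L, min(idx[, ax]) - pad_vox[ax])
    hi <- min(d[ax], max(idx[, ax]) + pad_vox[ax])
    as.integer(c(lo, hi))
  }
  new_voi(rng(1), rng(2), rng(3), as.integer(seed))
}

#' Read manual VOI boxes from a CSV file
#'
#' Schema: `nodule_id, slice_min, slice_max, row_min, row_max, col_min,
#' col_max`, 0-based inclusive voxel indices (converted to the package's
#' 1-based convention on read). This is the override path mirroring the
#' manually drawn nodule boxes of the clinical workflow.
#'
#' @param path CSV file path.
#' @return Named list of `pet_voi` objects keyed by nodule id.
#' @export
read_voi_table <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("nodule_id", "slice_min", "slice_max", "row_min", "row_max",
            "col_min", "col_max")
  if (!all(need %in% names(tb))) {
    abort(paste("VOI table must have columns:", paste(need, collapse = ", ")))
  }
  vois <- purrr::pmap(tb[need], function(nodule_id, slice_min, slice_max,
                                         row_min, row_max, col_min, col_max) {
    v <- new_voi(as.integer(c(slice_min, slice_max)) + 1L,
                 as.integer(c(row_min, row_max)) + 1L,
                 as.integer(c(col_min, col_max)) + 1L,
                 as.integer(c(slice_min + 1L, row_min + 1L, col_min + 1L)))
    v$seed_voxel <- NULL
    v
  })
  setNames(vois, tb$nodule_id)
}
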