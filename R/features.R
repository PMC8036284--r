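# The four ordinal visual features measured on per-slice contour trees:
#   I   degree of nesting of uptake contours          (scale 1-4, w = 0.6)
#   II  change in contour shape across slices         (scale 1-3, w = 0.3)
#   III shift of the maximum-uptake locus             (scale 1-3, w = 0.05)
#   IV  size of the contour enclosing the maximum     (scale 1-3, w = 0.05)
# Features were scored visually in the clinical workflow; the functions
# here are the package's quantitative proxies, with all binning thresholds
# collected in one `binning_config()` so manual score tables and automated
# extraction are interchangeable inputs to the ranking stage.

tree_mask <- function(tree, pixels) {
  m <- matrix(FALSE, tree$window_dim[1], tree$window_dim[2])
  m[pixels] <- TRUE
  m
}

# root (level-1) node containing the slice maximum, or NULL
outer_node <- function(tree) {
  nd <- tree$nodes
  if (nrow(nd) == 0 || is.na(tree$global_max_index)) return(NULL)
  cand <- nd[nd$level == 1L & nd$contains_global_max, ]
  if (nrow(cand) == 0) return(NULL)
  cand[1, ]
}

# innermost (smallest) node containing the slice maximum, or NULL
innermost_node <- function(tree) {
  nd <- tree$nodes
  if (nrow(nd) == 0 || is.na(tree$global_max_index)) return(NULL)
  cand <- nd[nd$contains_global_max, ]
  if (nrow(cand) == 0) return(NULL)
  cand[which.min(cand$area_mm2), ]
}

#' Feature I: degree of nesting of uptake contours
#'
#' The highest number of contours nested one within another anywhere in
#' the slice sequence (the longest containment chain over all per-slice
#' trees).
#'
#' @param trees List of `contour_tree` objects, one per slice.
#' @return Integer nesting depth (0 when all trees are empty).
#' @export
nesting_degree <- function(trees) {
  if (length(trees) == 0) abort("need at least one contour tree")
  max(vapply(trees, tree_depth, 0L))
}

#' Feature II: change in the shape of uptake contours
#'
#' For each pair of consecutive slices, the outer nodule contours (the
#' root component holding each slice's maximum) are aligned on their
#' centroids, isotropically rescaled to a common area, and compared by
#' Jaccard overlap; the feature is the mean of `1 - overlap` across pairs.
#' Pairs where either slice has no contour are skipped. Invariant to
#' translation and to in-plane scale by construction: bulk respiratory
#' displacement and the axial taper every blob shows towards its poles
#' (concentric contours of shrinking area but unchanged shape) do not
#' register -- only genuine alteration of the contour's shape does.
#'
#' @param trees List of `contour_tree` objects (>= 2 slices).
#' @return Value in \[0, 1\], or `NA` with a warning when fewer than two
#'   slices have an outer contour (undefined; binned to score 1).
#' @export
shape_change <- function(trees) {
  outers <- lapply(trees, outer_node)
  have <- !vapply(outers, is.null, TRUE)
  vals <- c()
  for (i in seq_len(length(trees) - 1L)) {
    if (!have[i] || !have[i + 1L]) next
    a <- tree_mask(trees[[i]], outers[[i]]$pixels[[1]])
    b <- tree_mask(trees[[i + 1L]], outers[[i + 1L]]$pixels[[1]])
    vals <- c(vals, 1 - mask_shape_overlap(a, b))
  }
  if (length(vals) == 0) {
    warn("shape change undefined: fewer than two slices with an outer contour")
    return(NA_real_)
  }
  mean(vals)
}

# Jaccard overlap of two masks after centroid alignment and isotropic
# rescaling of the second mask to the area of the first (nearest-neighbour
# resampling about the centroid)
mask_shape_overlap <- function(a, b) {
  ia <- which(a, arr.ind = TRUE)
  ib <- which(b, arr.ind = TRUE)
  ca <- colMeans(ia)
  cb <- colMeans(ib)
  s <- sqrt(nrow(ib) / nrow(ia))  # maps A-frame lengths to B-frame lengths
  nr <- nrow(a); nc <- ncol(a)
  # sample B at the back-mapped position of every A-frame pixel
  pr <- matrix(seq_len(nr), nr, nc)
  pc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  br <- round((pr - ca[1]) * s + cb[1])
  bc <- round((pc - ca[2]) * s + cb[2])
  inside <- br >= 1 & br <= nrow(b) & bc >= 1 & bc <= ncol(b)
  b_al <- matrix(FALSE, nr, nc)
  b_al[inside] <- b[cbind(br[inside], bc[inside])]
  sum(a & b_al) / sum(a | b_al)
}

# translate a logical mask by integer (rows, cols); pixels shifted in from
# outside are FALSE
shift_mask <- function(m, by) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) - by[1]; cs <- seq_len(nc) - by[2]
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Feature III: shift of the maximum-uptake locus
#'
#' Maximum over consecutive slice pairs of the in-plane displacement (mm)
#' of the per-slice uptake maximum, normalised by the nodule equivalent
#' radius (radius of the circle matching the largest outer-contour area in
#' the sequence).
#'
#' @param trees List of `contour_tree` objects (>= 2 slices).
#' @return Nonnegative value, or `NA` with a warning when fewer than two
#'   slices have a located maximum.
#' @export
max_shift <- function(trees) {
  locs <- lapply(trees, function(tr) {
    if (is.na(tr$global_max_index) || nrow(tr$nodes) == 0) return(NULL)
    if (!any(tr$nodes$contains_global_max)) return(NULL)
    nr <- tr$window_dim[1]
    idx <- tr$global_max_index
    c(row = ((idx - 1L) %% nr) + 1L, col = ((idx - 1L) %/% nr) + 1L)
  })
  have <- !vapply(locs, is.null, TRUE)
  areas <- unlist(lapply(trees, function(tr) {
    o <- outer_node(tr)
    if (is.null(o)) NULL else o$area_mm2
  }))
  if (sum(have) < 2 || length(areas) == 0) {
    warn("max shift undefined: fewer than two slices with a located maximum")
    return(NA_real_)
  }
  eq_radius <- sqrt(max(areas) / pi)
  shifts <- c()
  for (i in seq_len(length(trees) - 1L)) {
    if (!have[i] || !have[i + 1L]) next
    shifts <- c(shifts, sqrt(sum((locs[[i]] - locs[[i + 1L]])^2)))
  }
  if (length(shifts) == 0) {
    warn("max shift undefined: no consecutive slice pair with located maxima")
    return(NA_real_)
  }
  max(shifts) / eq_radius
}

#' Feature IV: size of the contour enclosing the maximum uptake
#'
#' The largest area (mm^2), over the slice sequence, of the smallest
#' contour that directly surrounds the per-slice uptake maximum.
#'
#' @param trees List of `contour_tree` objects.
#' @return Area in mm^2 (0 when no slice has a maximum above level 1).
#' @export
max_contour_size <- function(trees) {
  areas <- unlist(lapply(trees, function(tr) {
    n <- innermost_node(tr)
    if (is.null(n)) NULL else n$area_mm2
  }))
  if (length(areas) == 0) 0 else max(areas)
}

#' Raw features of one nodule from its per-slice contour trees
#'
#' @param trees List of `contour_tree` objects for one nodule.
#' @param nodule_id Identifier carried into the output row.
#' @return One-row tibble: nodule_id, nesting_depth, shape_change,
#'   max_shift, max_contour_area_mm2.
#' @export
extract_features <- function(trees, nodule_id = "nodule") {
  tibble::tibble(
    nodule_id = nodule_id,
    nesting_depth = nesting_degree(trees),
    shape_change = shape_change(trees),
    max_shift = max_shift(trees),
    max_contour_area_mm2 = max_contour_size(trees))
}

#' Binning thresholds for the ordinal scales
#'
#' All cut points used to map raw feature measurements onto the ordinal
#' scales live here, so that automated extraction and manual visual scores
#' are interchangeable. Defaults: shape change < 0.15 slight / < 0.35
#' moderate / else considerable; normalised max shift < 0.2 slight / < 0.5
#' distinct / else considerable; contour size binned by cohort terciles
#' (`v4_thresholds = NULL`) or by fixed area cut points in mm^2.
#'
#' @param v2_thresholds,v3_thresholds Two increasing cut points each.
#' @param v4_thresholds `NULL` for cohort terciles, else two increasing
#'   area cut points (mm^2).
#' @return A `binning_config` list.
#' @export
binning_config <- function(v2_thresholds = c(0.15, 0.35),
                           v3_thresholds = c(0.2, 0.5),
                           v4_thresholds = NULL) {
  for (th in list(v2_thresholds, v3_thresholds)) {
    if (length(th) != 2L || diff(th) <= 0) {
      abort("binning thresholds must be two strictly increasing values")
    }
  }
  if (!is.null(v4_thresholds) &&
      (length(v4_thresholds) != 2L || diff(v4_thresholds) <= 0)) {
    abort("`v4_thresholds` must be NULL or two strictly increasing values")
  }
  structure(list(v2_thresholds = v2_thresholds,
                 v3_thresholds = v3_thresholds,
                 v4_thresholds = v4_thresholds),
            class = "binning_config")
}

#' Bin raw feature measurements onto the ordinal scales
#'
#' Nesting depth maps 0-1 to 1 ("no nesting"), 2 to 2, 3 to 3 and >= 4 to
#' 4; shape change and max shift are cut at the config thresholds; contour
#' size is scored by cohort terciles unless fixed thresholds are given.
#' Undefined (`NA`) shape change or shift degrades to score 1. Monotone
#' non-decreasing in every raw measurement.
#'
#' @param raw Tibble from [extract_features()] (one row per nodule).
#' @param config A [binning_config()].
#' @param label Optional character vector of known labels
#'   ("malignant"/"benign"), recycled onto the output.
#' @return Tibble: nodule_id, v1, v2, v3, v4, label.
#' @export
bin_features <- function(raw, config = binning_config(), label = NA_character_) {
  cut3 <- function(x, th) {
    s <- ifelse(is.na(x), 1L, 1L + (x >= th[1]) + (x >= th[2]))
    as.integer(s)
  }
  v4 <- if (is.null(config$v4_thresholds)) {
    if (nrow(raw) == 1L) {
      warn("cohort terciles undefined for a single nodule; v4 set to 2")
      2L
    } else {
      q <- quantile(raw$max_contour_area_mm2, c(1 / 3, 2 / 3), names = FALSE)
      cut3(raw$max_contour_area_mm2, q)
    }
  } else {
    cut3(raw$max_contour_area_mm2, config$v4_thresholds)
  }
  tibble::tibble(
    nodule_id = raw$nodule_id,
    v1 = pmin(pmax(raw$nesting_depth, 1L), 4L),
    v2 = cut3(raw$shape_change, config$v2_thresholds),
    v3 = cut3(raw$max_shift, config$v3_thresholds),
    v4 = v4,
    label = rep_len(label, nrow(raw)))
}

#' Read a manually scored feature table
#'
#' CSV schema: `nodule_id, v1, v2, v3, v4` plus an optional `label`
#' column. Scores outside their ordinal scales (v1 in 1..4, v2-v4 in 1..3)
#' are rejected with the offending row number.
#'
#' @param path CSV file path.
#' @return Tibble of validated feature records.
#' @export
read_feature_table <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("nodule_id", "v1", "v2", "v3", "v4")
  if (nrow(tb) == 0) {
    return(tibble::tibble(nodule_id = character(), v1 = integer(),
                          v2 = integer(), v3 = integer(), v4 = integer(),
                          label = character()))
  }
  if (!all(need %in% names(tb))) {
    abort(paste("feature table must have columns:", paste(need, collapse = ", ")))
  }
  validate_feature_scores(tb, where = path)
  if (!"label" %in% names(tb)) tb$label <- NA_character_
  tb[c(need, "label")]
}

validate_feature_scores <- function(tb, where = "feature table") {
  bad1 <- which(!tb$v1 %in% 1:4)
  bad234 <- which(!(tb$v2 %in% 1:3) | !(tb$v3 %in% 1:3) | !(tb$v4 %in% 1:3))
  bad <- sort(unique(c(bad1, bad234)))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: scores out of scale (v1 in 1..4, v2-v4 in 1..3) at row(s) %s",
      where, paste(bad, collapse = ", ")))
  }
  invisible(tb)
}
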