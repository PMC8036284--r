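# The uptake-contour transform: resample an axial PET slice to 1 mm
# isotropic pixels, min-max normalise to [0, 1], and either render the
# grayscale contour image (8-bit banding with the least-significant-bit
# OR step) or build the explicit superlevel-set containment tree that the
# ordinal features are measured on.

new_slice_image <- function(values, spacing_mm = 1, provenance = NA_integer_) {
  structure(list(values = values, spacing_mm = spacing_mm,
                 provenance = provenance),
            class = "slice_image")
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf("<slice_image> %dx%d at %.4g mm, values [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), x$spacing_mm,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Resample a slice to 1 mm isotropic pixels
#'
#' Bilinear, pixel-centre aligned, edge-clamped resampling from the
#' scanner grid to a 1 x 1 mm grid. The output side length is the physical
#' extent rounded half away from zero, so a 192 x 192 matrix at 3.6458 mm
#' becomes 700 x 700. A constant slice stays exactly constant and the
#' physical extent is preserved to the nearest mm.
#'
#' @param raw 2-D numeric matrix (one axial slice).
#' @param spacing_mm Input pixel spacing in mm (square pixels).
#' @param provenance Optional source slice index carried along.
#' @return A `slice_image` with `spacing_mm = 1`.
#' @export
resample_slice <- function(raw, spacing_mm, provenance = NA_integer_) {
  stopifnot_scalar_number(spacing_mm, "spacing_mm", positive = TRUE)
  if (!is.matrix(raw)) abort("`raw` must be a matrix.")
  out_dims <- as.integer(round_half_away(dim(raw) * spacing_mm))
  if (all(out_dims == dim(raw)) && abs(spacing_mm - 1) < 1e-12) {
    return(new_slice_image(raw, 1, provenance))
  }
  map <- resample_map(dim(raw), spacing_mm, out_dims)
  new_slice_image(apply_resample(raw, map), 1, provenance)
}

# precompute the bilinear index/weight map from input dims to output dims;
# reusable across slices of one series
resample_map <- function(in_dims, spacing_mm, out_dims) {
  axis_map <- function(n_in, n_out) {
    x <- mm_to_index(seq_len(n_out) - 0.5, spacing_mm)  # input index coords
    x <- pmin(pmax(x, 1), n_in)
    i0 <- pmin(floor(x), n_in - 1L)
    if (n_in == 1L) i0 <- rep(1L, n_out)
    w <- x - i0
    list(i0 = as.integer(i0), i1 = as.integer(pmin(i0 + 1L, n_in)), w = w)
  }
  list(r = axis_map(in_dims[1], out_dims[1]),
       c = axis_map(in_dims[2], out_dims[2]))
}

apply_resample <- function(raw, map) {
  r <- map$r; cc <- map$c
  w_r <- r$w; w_c <- cc$w
  m00 <- raw[r$i0, cc$i0, drop = FALSE]
  m10 <- raw[r$i1, cc$i0, drop = FALSE]
  m01 <- raw[r$i0, cc$i1, drop = FALSE]
  m11 <- raw[r$i1, cc$i1, drop = FALSE]
  wr <- matrix(w_r, length(w_r), length(w_c))
  wc <- matrix(w_c, length(w_r), length(w_c), byrow = TRUE)
  m00 * (1 - wr) * (1 - wc) + m10 * wr * (1 - wc) +
    m01 * (1 - wr) * wc + m11 * wr * wc
}

#' Min-max normalise a slice image to \[0, 1\]
#'
#' `(x - min) / (max - min)`; a constant slice maps to all zeros (a flat
#' slice carries no contours, and this avoids a division by zero).
#'
#' @param image A `slice_image` or plain matrix.
#' @return A `slice_image` with values in \[0, 1\].
#' @export
normalize_slice <- function(image) {
  v <- if (inherits(image, "slice_image")) image$values else image
  if (!all(is.finite(v))) abort("slice contains non-finite values")
  rng <- range(v)
  v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else
    array(0, dim = dim(v))
  if (inherits(image, "slice_image")) {
    new_slice_image(v, image$spacing_mm, image$provenance)
  } else {
    new_slice_image(v, 1)
  }
}

#' Render the grayscale contour image of a normalised slice
#'
#' Literal mode reproduces the published transform byte-for-byte: the
#' normalised value is quantised to 8 bits, OR-ed with a matrix of ones
#' (setting the least-significant bit, which merges adjacent intensity
#' pairs into bands), used as a transparency channel for black ink over a
#' white background: `gray = 255 - (round(255 v) | 1)`. Explicit mode
#' additionally draws the superlevel-set boundaries at thresholds
#' `k/levels` in black, making the banded contour structure unambiguous.
#'
#' @param image Normalised `slice_image` (values in \[0, 1\]).
#' @param mode `"literal"` or `"explicit"`.
#' @param levels Number of quantisation bands for explicit boundaries.
#' @param path Optional output path; when given, the image is written as an
#'   8-bit grayscale PNG.
#' @return Integer matrix of gray values 0..255 (invisibly when `path` is
#'   given).
#' @export
render_contour_png <- function(image, mode = c("literal", "explicit"),
                               levels = 256L, path = NULL) {
  mode <- match.arg(mode)
  v <- if (inherits(image, "slice_image")) image$values else image
  if (min(v) < 0 || max(v) > 1) abort("image must be normalised to [0, 1]")
  q <- round(255 * v)
  g <- matrix(255L - bitwOr(as.integer(q), 1L), nrow(v), ncol(v))
  if (mode == "explicit") {
    for (k in seq_len(levels - 1L)) {
      g[boundary_mask(v >= k / levels)] <- 0L
    }
  }
  if (!is.null(path)) {
    png::writePNG(g / 255, path)
    return(invisible(g))
  }
  g
}

# pixels of `mask` with a 4-neighbour inside the image but outside the
# mask: the rasterised boundary of the superlevel set (threshold
# crossings only -- the image frame itself is not a contour)
boundary_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  shift <- function(m, dr, dc) {
    out <- matrix(TRUE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  nb_all <- shift(mask, 1, 0) & shift(mask, -1, 0) &
    shift(mask, 0, 1) & shift(mask, 0, -1)
  mask & !nb_all
}

# --- contour tree ----------------------------------------------------------

#' Build the per-slice iso-contour containment tree
#'
#' Computes the connected components ("uptake contours") of the superlevel
#' sets `{v >= k/levels}` for `k = 1..levels-1` on the slice restricted to
#' the VOI window, links each component to the enclosing component at the
#' next lower level, and locates the local uptake maxima, flagging the
#' window's global maximum (the "maximum emission"). In-plane components
#' use 4-connectivity; areas are pixel counts in mm^2 (1 mm pixels).
#'
#' @param image Normalised `slice_image` at 1 mm spacing.
#' @param voi Optional `pet_voi` whose row/col ranges are **already in
#'   resampled (1 mm) coordinates**, or `NULL` for the whole slice.
#' @param levels Number of quantisation levels (default 8).
#' @return A `contour_tree`: `nodes` tibble (id, level, parent, area_mm2,
#'   centroid, pixel and boundary-pixel index lists, contains_global_max),
#'   `maxima` tibble, window origin, and bookkeeping fields.
#' @export
build_contour_tree <- function(image, voi = NULL, levels = 8L) {
  v <- if (inherits(image, "slice_image")) image$values else image
  if (min(v) < -1e-9 || max(v) > 1 + 1e-9) {
    abort("image must be normalised to [0, 1]")
  }
  if (!is.null(voi)) {
    rr <- voi$row_range; cr <- voi$col_range
    if (rr[1] > rr[2] || cr[1] > cr[2]) abort("empty VOI window")
    v <- v[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
    origin <- c(rr[1], cr[1])
  } else {
    origin <- c(1L, 1L)
  }
  nr <- nrow(v); nc <- ncol(v)
  label_stack <- vector("list", levels - 1L)
  nodes <- list()
  id_of <- list()  # per level: label -> node id (possibly a merged ancestor)
  next_id <- 1L
  for (k in seq_len(levels - 1L)) {
    mask <- v >= k / levels
    lab <- if (any(mask)) ebi_label(mask) else matrix(0L, nr, nc)
    label_stack[[k]] <- lab
    nlab <- max(lab)
    ids <- integer(nlab)
    for (l in seq_len(nlab)) {
      pix <- which(lab == l)
      parent <- NA_integer_
      if (k > 1L) {
        parent_lab <- label_stack[[k - 1L]][pix[1]]
        parent <- id_of[[k - 1L]][parent_lab]
        # a component whose pixel set equals its parent's is the same
        # visible contour, not a new nesting level: merge it
        if (length(pix) == length(nodes[[parent]]$pixels)) {
          ids[l] <- parent
          next
        }
      }
      bmask <- matrix(FALSE, nr, nc)
      bmask[pix] <- TRUE
      bpix <- which(boundary_mask(bmask))
      rows <- ((pix - 1L) %% nr) + 1L
      cols <- ((pix - 1L) %/% nr) + 1L
      nodes[[next_id]] <- list(
        id = next_id, level = k, parent = parent,
        area_mm2 = length(pix),
        centroid_row_mm = mean(index_to_mm(rows, 1)),
        centroid_col_mm = mean(index_to_mm(cols, 1)),
        pixels = pix, boundary_pixels = bpix)
      ids[l] <- next_id
      next_id <- next_id + 1L
    }
    id_of[[k]] <- ids
    if (nlab == 0L) break  # higher levels are empty too
  }
  maxima <- local_maxima(v)
  # the global maximum is well defined for any non-constant window, even
  # when it sits on a plateau with no strict local maximum
  gmax_idx <- if (length(v) > 0 && max(v) > min(v)) which.max(v)[1] else
    NA_integer_
  nodes_tbl <- if (length(nodes) > 0) {
    tibble::tibble(
      id = vapply(nodes, `[[`, 0L, "id"),
      level = vapply(nodes, `[[`, 0L, "level"),
      parent = vapply(nodes, `[[`, 0L, "parent"),
      area_mm2 = vapply(nodes, `[[`, 0, "area_mm2"),
      centroid_row_mm = vapply(nodes, `[[`, 0, "centroid_row_mm"),
      centroid_col_mm = vapply(nodes, `[[`, 0, "centroid_col_mm"),
      pixels = lapply(nodes, `[[`, "pixels"),
      boundary_pixels = lapply(nodes, `[[`, "boundary_pixels"),
      contains_global_max = vapply(nodes, function(nd)
        !is.na(gmax_idx) && gmax_idx %in% nd$pixels, TRUE))
  } else {
    tibble::tibble(id = integer(), level = integer(), parent = integer(),
                   area_mm2 = numeric(), centroid_row_mm = numeric(),
                   centroid_col_mm = numeric(), pixels = list(),
                   boundary_pixels = list(), contains_global_max = logical())
  }
  structure(list(nodes = nodes_tbl, maxima = maxima,
                 window_origin = origin, window_dim = c(nr, nc),
                 levels = levels,
                 global_max_index = gmax_idx,
                 global_max_value = if (length(v)) max(v) else NA_real_),
            class = "contour_tree")
}

# 4-connectivity labelling via EBImage; returns integer label matrix
ebi_label <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}

# strict local maxima over the 8-neighbourhood
local_maxima <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 1 || nc < 1 || max(v) == min(v)) {
    return(tibble::tibble(row = integer(), col = integer(), value = numeric(),
                          is_global = logical()))
  }
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- v
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nbr <- pad[(2:(nr + 1)) + dr, (2:(nc + 1)) + dc, drop = FALSE]
    is_max <- is_max & (v > nbr)
  }
  idx <- which(is_max, arr.ind = TRUE)
  g <- which.max(v)[1]
  tibble::tibble(row = idx[, 1], col = idx[, 2],
                 value = v[is_max],
                 is_global = (idx[, 2] - 1L) * nr + idx[, 1] == g)
}

#' @export
print.contour_tree <- function(x, ...) {
  cat(sprintf("<contour_tree> %d nodes over %d levels, window %dx%d, depth %d\n",
              nrow(x$nodes), x$levels, x$window_dim[1], x$window_dim[2],
              tree_depth(x)))
  invisible(x)
}

#' Nesting depth of one contour tree
#'
#' Length of the longest root-to-leaf chain of *distinct* nested contours.
#' For a smooth unimodal field this equals the number of superlevel
#' thresholds below the window's peak value; plateaus that reproduce the
#' identical component at several thresholds count once.
#'
#' @param tree A `contour_tree`.
#' @return Integer depth (0 for an empty tree).
#' @export
tree_depth <- function(tree) {
  nd <- tree$nodes
  if (nrow(nd) == 0) return(0L)
  depth <- integer(nrow(nd))  # nodes are created parents-first
  for (i in seq_len(nrow(nd))) {
    depth[i] <- if (is.na(nd$parent[i])) 1L else depth[nd$parent[i]] + 1L
  }
  max(depth)
}

#' Validate contour-tree structural invariants
#'
#' Asserts that every child's pixel set is strictly contained in its
#' parent's, that components at one level are pairwise disjoint, that every
#' node above level 1 has exactly one parent, and that the global maximum
#' lies inside every ancestor of its leaf component. Used by the test suite
#' on every phantom tree; errors describe the first violated invariant.
#'
#' @param tree A `contour_tree`.
#' @return `TRUE` invisibly, or an error.
#' @export
validate_contour_tree <- function(tree) {
  nd <- tree$nodes
  if (nrow(nd) == 0) return(invisible(TRUE))
  by_id <- split(seq_len(nrow(nd)), nd$id)
  for (i in seq_len(nrow(nd))) {
    if (nd$level[i] > 1L) {
      if (is.na(nd$parent[i])) abort(sprintf("node %d has no parent", nd$id[i]))
      p <- which(nd$id == nd$parent[i])
      if (length(p) != 1L) abort(sprintf("node %d has %d parents", nd$id[i], length(p)))
      if (!all(nd$pixels[[i]] %in% nd$pixels[[p]])) {
        abort(sprintf("node %d not contained in its parent", nd$id[i]))
      }
      if (length(nd$pixels[[i]]) >= length(nd$pixels[[p]])) {
        abort(sprintf("node %d not strictly smaller than its parent", nd$id[i]))
      }
    } else if (!is.na(nd$parent[i])) {
      abort(sprintf("level-1 node %d has a parent", nd$id[i]))
    }
  }
  for (k in unique(nd$level)) {
    pix <- unlist(nd$pixels[nd$level == k])
    if (anyDuplicated(pix)) abort(sprintf("components at level %d overlap", k))
  }
  if (!is.na(tree$global_max_index)) {
    holders <- nd[nd$contains_global_max, ]
    if (nrow(holders) > 0) {
      deepest <- holders[which.max(holders$level), ]
      node <- deepest
      while (!is.na(node$parent)) {
        node <- nd[nd$id == node$parent, ]
        if (!node$contains_global_max) {
          abort("global max missing from an ancestor of its leaf component")
        }
      }
    }
  }
  invisible(TRUE)
}

#' Serialise contour trees to JSON
#'
#' One entry per slice; nodes carry level, area, centroid, parent id and
#' the global-max flag (pixel sets are omitted from the dump).
#'
#' @param trees List of `contour_tree` objects.
#' @param path Output JSON path.
#' @return `path` invisibly.
#' @export
write_contour_tree_json <- function(trees, path) {
  payload <- lapply(trees, function(tr) {
    list(levels = tr$levels,
         window_origin = tr$window_origin,
         depth = tree_depth(tr),
         nodes = dplyr::select(tr$nodes, -"pixels", -"boundary_pixels"))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
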