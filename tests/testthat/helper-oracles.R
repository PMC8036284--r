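# Independent oracles, coded without reference to the package internals.

# 4-connectivity connected-component labelling by BFS flood fill
bfs_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% nr) + 1L
      cl <- ((p - 1L) %/% nr) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- cl + d[2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        q <- (cc - 1L) * nr + rr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# literal triple-loop GDM2 evaluation: d_ik over context rows `ctx` of `x`
gdm2_oracle <- function(x, i, k, w, ctx = seq_len(nrow(x))) {
  x <- unname(as.matrix(x))
  w <- unname(w)
  p <- ncol(x)
  sgn <- function(a, b) sign(a - b)
  num <- 0
  for (j in seq_len(p)) {
    num <- num + w[j] * sgn(x[i, j], x[k, j]) * sgn(x[k, j], x[i, j])
  }
  for (j in seq_len(p)) {
    for (l in ctx) {
      if (l == i || l == k) next
      num <- num + w[j] * sgn(x[i, j], x[l, j]) * sgn(x[k, j], x[l, j])
    }
  }
  den_i <- 0; den_k <- 0
  for (j in seq_len(p)) {
    for (l in ctx) {
      if (l != i) den_i <- den_i + w[j] * sgn(x[i, j], x[l, j])^2
      if (l != k) den_k <- den_k + w[j] * sgn(x[k, j], x[l, j])^2
    }
  }
  den <- 2 * sqrt(den_i * den_k)
  if (den == 0) {
    if (all(x[i, ] == x[k, ])) return(0)
    stop("degenerate")
  }
  0.5 - num / den
}

# exhaustive maximum-gradient segmentation: best triple of gap indices by
# total gap size, lexicographically smallest on ties
max_gradient_oracle <- function(d) {
  s <- sort(d)
  gaps <- diff(s)
  combs <- utils::combn(length(gaps), 3)
  sums <- colSums(matrix(gaps[combs], nrow = 3))
  best <- which(sums > max(sums) - 1e-12)
  pick <- combs[, best[1]]  # combn enumerates in lexicographic order
  sort((s[pick] + s[pick + 1]) / 2)
}

# the full 4 x 3 x 3 x 3 grid of admissible ordinal records
exhaustive_grid <- function() {
  g <- expand.grid(v1 = 1:4, v2 = 1:3, v3 = 1:3, v4 = 1:3)
  tibble::tibble(nodule_id = sprintf("g%03d", seq_len(nrow(g))),
                 v1 = g$v1, v2 = g$v2, v3 = g$v3, v4 = g$v4)
}

# small single-focus phantom used across tests
simple_phantom <- function(seed = 1, noise_sd = 0, drift = c(0, 0),
                           amplitude = 1, sigma = 5, spacing = 1,
                           grid = c(7, 48, 48), suvmax = 5,
                           reference = NULL) {
  ctr <- c(grid[1] * 3.3 / 2, grid[2] * spacing / 2, grid[3] * spacing / 2)
  phantom_spec(
    grid_shape = grid, in_plane_spacing_mm = spacing,
    slice_thickness_mm = 3.3, background_activity = 0.1,
    noise_sd = noise_sd, nodule_center_mm = ctr, nodule_radius_mm = 10,
    foci = list(focus_spec(amplitude, sigma, ctr, drift)),
    seed = seed, suvmax = suvmax, reference = reference)
}
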