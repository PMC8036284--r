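# helper: build a contour tree directly from a value matrix
tree_of <- function(x, levels = 8L) build_contour_tree(x, levels = levels)

gauss2d <- function(n, ctr, sigma, peak = 1) {
  peak * exp(-(outer((seq_len(n) - ctr[1])^2, (seq_len(n) - ctr[2])^2, `+`)) /
               (2 * sigma^2))
}

test_that("nesting degree is the deepest chain over the slice sequence", {
  empty <- tree_of(matrix(0, 12, 12))
  expect_equal(nesting_degree(list(empty, empty)), 0L)
  deep <- tree_of(gauss2d(31, c(16, 16), 5, peak = 0.55))   # 4 thresholds below 0.55
  shallow <- tree_of(gauss2d(31, c(16, 16), 5, peak = 0.3)) # 2 below 0.3
  expect_equal(nesting_degree(list(shallow, deep, empty)), 4L)
  # noise-free phantom whose peak spans 3 level bands
  banded <- tree_of(gauss2d(31, c(16, 16), 6, peak = 0.45))
  expect_equal(nesting_degree(list(banded)), 3L)
})

test_that("shape change is zero for identical stacks and one for disjoint shapes", {
  a <- tree_of(gauss2d(31, c(16, 16), 5, 0.9))
  expect_equal(shape_change(list(a, a, a)), 0)
  # ring vs concentric dot: same centroid, same area, disjoint supports
  ring <- matrix(0, 21, 21)
  d2 <- outer((1:21 - 11)^2, (1:21 - 11)^2, `+`)
  ring[d2 >= 36 & d2 <= 64] <- 1
  n_ring <- sum(ring > 0)
  dot <- matrix(0, 21, 21)
  dot[rank(d2, ties.method = "first") <= n_ring] <- 1
  expect_equal(sum(dot > 0), n_ring)
  expect_equal(sum(ring * dot), 0)
  expect_equal(shape_change(list(tree_of(ring / 2 + 0.5 * ring),
                                 tree_of(dot / 2 + 0.5 * dot))), 1)
})

test_that("shape change between circle and 2:1 ellipse matches the pixel oracle", {
  n <- 61
  circ <- matrix(0, n, n); elli <- matrix(0, n, n)
  r <- 10
  for (i in 1:n) for (j in 1:n) {
    circ[i, j] <- as.numeric((i - 31)^2 + (j - 31)^2 <= r^2)
    elli[i, j] <- as.numeric((i - 31)^2 / (r / sqrt(2))^2 +
                               (j - 31)^2 / (r * sqrt(2))^2 <= 1)
  }
  val <- shape_change(list(tree_of(circ), tree_of(elli)))
  # oracle: independent rasterised overlap of the area-normalised masks
  a <- circ > 0; b <- elli > 0
  ca <- colMeans(which(a, arr.ind = TRUE))
  cb <- colMeans(which(b, arr.ind = TRUE))
  s <- sqrt(sum(b) / sum(a))
  inter <- 0; uni <- 0
  for (i in 1:n) for (j in 1:n) {
    bi <- round((i - ca[1]) * s + cb[1]); bj <- round((j - ca[2]) * s + cb[2])
    bij <- bi >= 1 && bi <= n && bj >= 1 && bj <= n && b[bi, bj]
    inter <- inter + (a[i, j] && bij)
    uni <- uni + (a[i, j] || bij)
  }
  expect_equal(val, 1 - inter / uni, tolerance = 1e-12)
  expect_gt(val, 0.2)  # a 2:1 ellipse is a genuine shape change
})

test_that("max shift follows the constructed focus displacement", {
  # static focus: shift ~ 0
  static <- lapply(1:4, function(s) tree_of(gauss2d(41, c(21, 21), 6, 0.9)))
  expect_lt(max_shift(static), 0.1)
  # focus hopping 8 mm with equivalent radius from a wide outer contour
  hop <- lapply(1:4, function(s)
    tree_of(gauss2d(41, c(21, 13 + 8 * (s %% 2)), 6, 0.9)))
  area <- max(vapply(hop, function(t) max(t$nodes$area_mm2[t$nodes$level == 1]), 0))
  eq_r <- sqrt(area / pi)
  expect_equal(max_shift(hop), 8 / eq_r, tolerance = 0.15)
  # alternating dominance between two fixed foci 12 mm apart: displacement
  # equals the exhaustive per-slice argmax distance
  two_foci <- function(w1, w2) {
    gauss2d(41, c(21, 15), 4, w1) + gauss2d(41, c(21, 27), 4, w2)
  }
  alt <- list(tree_of(two_foci(0.9, 0.6)), tree_of(two_foci(0.6, 0.9)),
              tree_of(two_foci(0.9, 0.6)))
  mats <- list(two_foci(0.9, 0.6), two_foci(0.6, 0.9), two_foci(0.9, 0.6))
  pos <- t(vapply(mats, function(m) arrayInd(which.max(m), dim(m))[1, ], c(0, 0)))
  d_oracle <- max(sqrt(rowSums(diff(pos)^2)))
  areas <- vapply(alt, function(t) max(t$nodes$area_mm2[t$nodes$level == 1]), 0)
  expect_equal(max_shift(alt), d_oracle / sqrt(max(areas) / pi),
               tolerance = 1e-12)
})

test_that("max contour size reports the largest innermost component", {
  # single-pixel peak inside a flat 100-pixel plateau: innermost contour
  # has exactly the plateau's 100 pixels
  x <- matrix(0, 30, 30)
  x[11:20, 11:20] <- 0.5
  x[15, 15] <- 0.5 + 1e-9   # locate the maximum without adding a level
  tr <- tree_of(x)
  expect_equal(max_contour_size(list(tr)), 100)
  expect_equal(max_contour_size(list(tree_of(matrix(0, 5, 5)))), 0)
  # Gaussian focus: area equals the pixel count of the top superlevel set
  g <- gauss2d(41, c(21, 21), 4, 0.99)
  tr2 <- tree_of(g)
  expect_equal(max_contour_size(list(tr2)), sum(g >= 7 / 8))
})

test_that("binning maps raw measurements onto the ordinal scales", {
  raw <- tibble::tibble(
    nodule_id = c("a", "b", "c", "d"),
    nesting_depth = c(0L, 2L, 3L, 7L),
    shape_change = c(0, 0.2, 0.14, 0.5),
    max_shift = c(0, 0.3, 0.19, 0.7),
    max_contour_area_mm2 = c(10, 40, 80, 200))
  rec <- bin_features(raw, binning_config(v4_thresholds = c(30, 100)))
  expect_equal(rec$v1, c(1L, 2L, 3L, 4L))
  expect_equal(rec$v2, c(1L, 2L, 1L, 3L))
  expect_equal(rec$v3, c(1L, 2L, 1L, 3L))
  expect_equal(rec$v4, c(1L, 2L, 2L, 3L))
  # undefined raw features degrade to score 1
  raw$shape_change[2] <- NA
  expect_equal(bin_features(raw, binning_config(v4_thresholds = c(30, 100)))$v2[2], 1L)
})

test_that("binning is monotone non-decreasing in each raw measurement", {
  set.seed(7)
  cfg <- binning_config(v4_thresholds = c(50, 150))
  for (i in 1:50) {
    base <- tibble::tibble(nodule_id = "x", nesting_depth = sample(0:8, 1),
                           shape_change = runif(1), max_shift = runif(1, 0, 2),
                           max_contour_area_mm2 = runif(1, 0, 300))
    bumped <- base
    j <- sample(2:5, 1)
    bumped[[j]] <- bumped[[j]] + runif(1, 0, 1)
    b0 <- bin_features(base, cfg)
    b1 <- bin_features(bumped, cfg)
    expect_true(all(unlist(b1[c("v1", "v2", "v3", "v4")]) >=
                      unlist(b0[c("v1", "v2", "v3", "v4")])))
  }
})

test_that("feature tables are validated row by row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("nodule_id,v1,v2,v3,v4,label",
               "n1,4,3,3,2,malignant",
               "n2,1,1,2,3,benign"), path)
  tb <- read_feature_table(path)
  expect_equal(nrow(tb), 2L)
  expect_equal(tb$v1, c(4, 1))
  writeLines(c("nodule_id,v1,v2,v3,v4", "n1,5,1,1,1"), path)
  expect_error(read_feature_table(path), "row\\(s\\) 1")
  writeLines("nodule_id,v1,v2,v3,v4", path)
  expect_equal(nrow(read_feature_table(path)), 0L)
})
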