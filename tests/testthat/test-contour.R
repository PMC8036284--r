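test_that("resampling reproduces the printed scanner geometry", {
  r <- resample_slice(matrix(runif(192 * 192), 192, 192), 3.6458)
  expect_equal(dim(r$values), c(700L, 700L))
  expect_equal(r$spacing_mm, 1)
})

test_that("resampling is the identity at 1 mm and preserves constants", {
  m <- matrix(runif(100 * 100), 100, 100)
  expect_identical(resample_slice(m, 1.0)$values, m)
  cst <- resample_slice(matrix(5, 50, 50), 2.0)
  expect_equal(dim(cst$values), c(100L, 100L))
  expect_true(all(cst$values == 5))
})

test_that("resampling preserves the mean of a smooth field within 1%", {
  x <- outer(seq_len(60), seq_len(60), function(i, j)
    1 + sin(i / 9) * cos(j / 11))
  r <- resample_slice(x, 3.3)
  expect_lt(abs(mean(r$values) - mean(x)) / mean(x), 0.01)
})

test_that("min-max normalisation maps onto [0, 1] and flattens constants", {
  n <- normalize_slice(matrix(c(3, 5, 7, 5), 2, 2))
  expect_equal(sort(unique(as.vector(n$values))), c(0, 0.5, 1))
  flat <- normalize_slice(matrix(4, 3, 3))
  expect_true(all(flat$values == 0))
  set.seed(1)
  rnd <- normalize_slice(matrix(rnorm(100), 10, 10))
  expect_equal(range(rnd$values), c(0, 1))
})

test_that("literal rendering follows the banding formula", {
  img <- new <- matrix(0, 4, 4)
  g0 <- render_contour_png(img)
  expect_true(all(g0 == 254L))  # 255 - (0 | 1)
  img[2, 2] <- 1
  g1 <- render_contour_png(img)
  expect_equal(g1[2, 2], 0L)    # 255 - (255 | 1)
  # the OR step merges adjacent quantisation pairs: 2k and 2k+1 render alike
  expect_equal(render_contour_png(matrix(2 / 255, 1, 1))[1, 1],
               render_contour_png(matrix(3 / 255, 1, 1))[1, 1])
})

test_that("explicit rendering of a linear ramp draws one line per threshold", {
  # ramp kept below full intensity so no pixel is black in the literal base
  v <- matrix(rep(seq(0, 0.95, length.out = 40), each = 40), 40, 40)
  g <- render_contour_png(v, mode = "explicit", levels = 4)
  dark <- g == 0L
  # brute force: boundary pixels must form exactly 3 connected lines
  expect_equal(max(bfs_label(dark)), 3L)
})

test_that("PNG files round-trip through the png reader", {
  img <- normalize_slice(matrix(runif(64), 8, 8))
  path <- withr::local_tempfile(fileext = ".png")
  g <- render_contour_png(img, path = path)
  back <- png::readPNG(path)
  expect_equal(round(back * 255), g, ignore_attr = TRUE)
})

test_that("a flat window yields an empty tree with no maxima", {
  tr <- build_contour_tree(matrix(0, 10, 10))
  expect_equal(nrow(tr$nodes), 0L)
  expect_equal(tree_depth(tr), 0L)
  expect_equal(nrow(tr$maxima), 0L)
})

test_that("two equal disjoint foci give two root components", {
  x <- matrix(0, 30, 60)
  for (i in 1:30) for (j in 1:60) {
    x[i, j] <- exp(-((i - 15)^2 + (j - 15)^2) / 18) +
      exp(-((i - 15)^2 + (j - 45)^2) / 18)
  }
  tr <- build_contour_tree(normalize_slice(x))
  roots <- tr$nodes[tr$nodes$level == 1 & is.na(tr$nodes$parent), ]
  expect_equal(nrow(roots), 2L)
  validate_contour_tree(tr)
})

test_that("chain length equals the threshold count below a Gaussian peak", {
  # brute-force oracle: label every superlevel set independently; the
  # chain through a unimodal peak holds one node per *distinct* nonempty
  # superlevel set, which for a smooth Gaussian is every threshold below
  # the peak value
  for (peak in c(0.3, 0.55, 0.9)) {
    x <- peak * exp(-(outer((1:41 - 21)^2, (1:41 - 21)^2, `+`)) / 72)
    tr <- build_contour_tree(x, levels = 8)
    masks <- lapply(seq_len(7), function(k) which(x >= k / 8))
    nonempty <- masks[vapply(masks, length, 0L) > 0]
    distinct <- length(nonempty) -
      sum(vapply(seq_len(length(nonempty) - 1), function(i)
        identical(nonempty[[i]], nonempty[[i + 1]]), TRUE))
    expect_equal(tree_depth(tr), distinct)
    expect_equal(distinct, sum(seq_len(7) / 8 <= peak))
    # total node count matches the oracle's count of distinct components
    total <- 0L
    prev <- NULL
    for (k in seq_len(7)) {
      lab <- bfs_label(x >= k / 8)
      for (l in seq_len(max(lab))) {
        pix <- which(lab == l)
        is_new <- is.null(prev) ||
          length(pix) != sum(prev == prev[pix[1]]) || prev[pix[1]] == 0L
        if (is_new) total <- total + 1L
      }
      prev <- lab
    }
    expect_equal(nrow(tr$nodes), total)
  }
})

test_that("tree boundary pixels lie on explicit-mode drawn boundaries", {
  set.seed(21)
  x <- normalize_slice(matrix(stats::filter(rnorm(900), rep(1, 5)/5,
                                            circular = TRUE), 30, 30))
  g <- render_contour_png(x, mode = "explicit", levels = 8)
  tr <- build_contour_tree(x, levels = 8)
  for (i in seq_len(nrow(tr$nodes))) {
    bp <- tr$nodes$boundary_pixels[[i]]
    expect_true(all(g[bp] == 0L))
  }
})

test_that("structural invariants hold on phantom trees", {
  ch <- generate_cohort(2, 2, seed = 33)
  cfg <- pipeline_config()
  for (i in seq_along(ch$series)) {
    voi <- manifest_vois(ch$manifest)[[i]]
    tr <- transform_series(ch$series[[i]], cfg, voi = voi)
    for (t in tr$trees) expect_no_error(validate_contour_tree(t))
  }
})
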