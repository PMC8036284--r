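test_that("GDM2 reproduces hand-evaluated single-variable distances", {
  x <- matrix(c(1, 2, 3), ncol = 1)
  expect_equal(gdm2_distance(x, 1, 2), 0.5)
  expect_equal(gdm2_distance(x, 1, 3), 1.0)
  expect_equal(gdm2_distance(x, 2, 3), 0.5)
  # identical profiles in a nondegenerate context
  y <- matrix(c(2, 2, 1, 3), ncol = 1)
  expect_equal(gdm2_distance(y, 1, 2), 0)
  # identical profiles in a fully tied context: distance 0, no error
  expect_equal(gdm2_distance(matrix(c(1, 1), ncol = 1), 1, 2), 0)
  # an all-tied cohort distinct from the pattern has no sign variation to
  # normalise by when the pattern is kept out of the context
  tied <- tibble::tibble(nodule_id = c("a", "b"), v1 = c(1L, 1L),
                         v2 = c(1L, 1L), v3 = c(1L, 1L), v4 = c(1L, 1L))
  expect_error(synthetic_variable(tied, include_pattern = FALSE),
               "degenerate")
  expect_no_error(synthetic_variable(tied, include_pattern = TRUE))
})

test_that("optimized GDM2 equals the literal brute-force oracle", {
  set.seed(31)
  w4 <- c(0.6, 0.3, 0.05, 0.05)
  for (rep in 1:40) {
    n <- sample(3:12, 1)
    x <- matrix(sample(1:4, n * 4, replace = TRUE), n, 4)
    i <- sample(n, 1)
    k <- sample(setdiff(seq_len(n), i), 1)
    d_opt <- gdm2_distance(x, i, k, w4)
    d_orc <- tryCatch(gdm2_oracle(x, i, k, w4), error = function(e) NULL)
    if (is.null(d_orc)) next
    expect_equal(d_opt, d_orc, tolerance = 1e-12)
  }
})

test_that("GDM2 is symmetric, bounded and zero on the diagonal (108 grid)", {
  grid <- exhaustive_grid()
  x <- as.matrix(grid[paste0("v", 1:4)])
  d <- gdm2_pairwise(x, c(0.6, 0.3, 0.05, 0.05))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("the anti-pattern record attains the cohort maximum distance", {
  grid <- exhaustive_grid()
  scored <- synthetic_variable(grid)
  worst <- scored[scored$v1 == 1 & scored$v2 == 1 & scored$v3 == 1, ]
  expect_equal(max(worst$distance), max(scored$distance))
  expect_true(all(scored$distance >= 0 & scored$distance <= 1))
  # a record equal to the pattern profile sorts first at distance 0
  pat <- scored[scored$v1 == 4 & scored$v2 == 3 & scored$v3 == 3 &
                  scored$v4 == 2, ]
  expect_equal(pat$distance, 0)
  expect_equal(min(scored$distance), 0)
})

test_that("distances are invariant to cohort input order", {
  set.seed(17)
  rec <- exhaustive_grid()[sample(108, 20), ]
  a <- synthetic_variable(rec)
  perm <- sample(nrow(rec))
  b <- synthetic_variable(rec[perm, ])
  expect_equal(a$distance[perm], b$distance)
})

test_that("pattern object honours scale maxima and the neutral reference", {
  expect_equal(unlist(pattern_object()[paste0("v", 1:4)]),
               c(v1 = 4L, v2 = 3L, v3 = 3L, v4 = 2L))
  all_stim <- scale_specs(types = rep("stimulant", 4))
  expect_equal(unlist(pattern_object(all_stim)[paste0("v", 1:4)]),
               c(v1 = 4L, v2 = 3L, v3 = 3L, v4 = 3L))
  expect_no_error(validate_feature_scores(pattern_object()))
})

test_that("maximum-gradient segmentation splits at the three largest gaps", {
  d <- c(0.10, 0.12, 0.30, 0.32, 0.50, 0.52, 0.90)
  g <- max_gradient_groups(d)
  expect_equal(g$boundaries, c(0.21, 0.41, 0.71))
  expect_equal(as.vector(table(g$group)), c(2, 2, 2, 1))
  # equal gaps (binary-exact quarter steps): earliest-index gaps win
  tie <- max_gradient_groups(seq(0, 1.25, by = 0.25))
  expect_equal(tie$boundaries, c(0.125, 0.375, 0.625))
  expect_error(max_gradient_groups(c(0.1, 0.1, 0.2, 0.3)), "4 distinct")
})

test_that("grouping equals exhaustive search over boundary triples", {
  set.seed(47)
  for (rep in 1:50) {
    n <- sample(5:30, 1)
    d <- runif(n)
    g <- max_gradient_groups(d)
    expect_equal(g$boundaries, max_gradient_oracle(d), tolerance = 1e-12)
    # groups partition the cohort into intervals of the sorted order
    ord <- order(d)
    expect_true(all(diff(as.integer(g$group[ord])) >= 0))
    expect_equal(sum(table(g$group)), n)
  }
})

test_that("classification at 0.4 is boundary-inclusive toward malignancy", {
  expect_equal(classify_nodules(c(0, 0.4, 0.400001, 1)),
               c("malignant", "malignant", "benign", "benign"))
})

test_that("summary arithmetic reproduces the published group percentages", {
  comp <- tibble::tibble(
    group = factor(c("I", "II", "III", "IV"), ordered = TRUE),
    n_malignant = c(33L, 6L, 1L, 0L),
    n_benign = c(0L, 1L, 10L, 18L))
  sm <- summarize_groups(comp)
  expect_equal(sm$rounded$pct_confident, 73.9)
  expect_equal(sm$rounded$pct_indeterminate, 26.1)
  expect_equal(sm$rounded$accuracy_at_threshold, 97.5)
  expect_equal(sm$rounded$malignant_share_pct, c(82.5, 15, 2.5, 0))
  expect_equal(sm$rounded$benign_share_pct, c(0, 3.4, 34.5, 62.1))
  expect_equal(round(sm$shares$benign_share_pct[4]), 62)
  # degenerate: everything confidently in one group
  one <- tibble::tibble(group = factor(c("I", "II", "III", "IV"), ordered = TRUE),
                        n_malignant = c(12L, 0L, 0L, 0L),
                        n_benign = c(0L, 0L, 0L, 0L))
  sm1 <- summarize_groups(one)
  expect_equal(sm1$pct_confident, 100)
  expect_equal(sm1$accuracy_at_threshold, 100)
})

test_that("ranking a table containing the pattern profile places it first", {
  rec <- tibble::tibble(
    nodule_id = c("p", "a", "b", "c", "d"),
    v1 = c(4L, 3L, 2L, 1L, 1L), v2 = c(3L, 2L, 2L, 1L, 3L),
    v3 = c(3L, 2L, 1L, 1L, 2L), v4 = c(2L, 1L, 2L, 3L, 1L))
  rk <- rank_cohort(rec)
  td <- tidy(rk)
  expect_equal(td$nodule_id[1], "p")
  expect_equal(td$distance[1], 0)
  expect_equal(as.character(td$group[1]), "I")
})

test_that("rankings degrade gracefully below four distinct distances", {
  rec <- tibble::tibble(nodule_id = c("a", "b", "c"),
                        v1 = c(4L, 2L, 1L), v2 = c(3L, 2L, 1L),
                        v3 = c(3L, 2L, 1L), v4 = c(2L, 2L, 2L))
  expect_warning(rk <- rank_cohort(rec), "4 distinct")
  td <- tidy(rk)
  expect_equal(nrow(td), 3L)
  expect_true(all(is.finite(td$distance)))
  expect_true(all(is.na(td$group)))
  expect_null(rk$boundaries)
})
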