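# Linear ordering of nodules by a GDM2 synthetic variable.
#
# GDM2 is the generalised distance measure for ordinal data: objects are
# compared only through the signs of their coordinate differences against
# every object in the analysed set, so the distance between two objects
# depends on the whole context. For objects i and k over variables j with
# weights w_j:
#
#   d_ik = 1/2 - [ sum_j w_j a_ikj b_kij
#                  + sum_j sum_{l != i,k} w_j a_ilj b_klj ]
#          / ( 2 * sqrt( sum_j sum_{l != i} w_j a_ilj^2
#                        * sum_j sum_{l != k} w_j b_klj^2 ) )
#
# with a_ipj = sgn(x_ij - x_pj) and b_krj = sgn(x_kj - x_rj). d is
# symmetric, lies in [0, 1], and is 0 for identical profiles. The
# synthetic variable of a nodule is its GDM2 distance from the pattern
# object (the ideal profile); smaller distance = more malignant-like.

#' Ordinal scale specification of the four diagnostic variables
#'
#' Scale bounds, a-priori weights and variable types: nesting degree
#' (1-4, weight 0.6, stimulant), shape change (1-3, 0.3, stimulant),
#' maximum-uptake shift (1-3, 0.05, stimulant), enclosing-contour size
#' (1-3, 0.05, neutral). Weights sum to 1.
#'
#' @param weights Numeric length-4 weights.
#' @param types Character length-4 of "stimulant"/"neutral".
#' @return Tibble: variable, name, scale_max, weight, type.
#' @export
scale_specs <- function(weights = c(0.6, 0.3, 0.05, 0.05),
                        types = c("stimulant", "stimulant", "stimulant",
                                  "neutral")) {
  if (length(weights) != 4L || any(weights <= 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    abort("`weights` must be four positive values summing to 1")
  }
  if (!all(types %in% c("stimulant", "neutral")) || length(types) != 4L) {
    abort("`types` must be four of 'stimulant'/'neutral'")
  }
  tibble::tibble(
    variable = 1:4,
    name = c("nesting", "shape_change", "max_shift", "max_contour_size"),
    scale_max = c(4L, 3L, 3L, 3L),
    weight = weights,
    type = types)
}

#' The pattern object of the linear ordering
#'
#' The ideal reference profile distances are measured from: each stimulant
#' variable at its scale maximum; the neutral variable at a configurable
#' reference value (default 2, its scale midpoint -- a neutral variable
#' has no preferred direction but still enters the distance with its
#' weight).
#'
#' @param scales A [scale_specs()] tibble.
#' @param neutral_value Reference value for neutral variables.
#' @return One-row tibble with columns v1..v4 and `nodule_id = "pattern"`.
#' @export
pattern_object <- function(scales = scale_specs(), neutral_value = 2L) {
  vals <- ifelse(scales$type == "stimulant", scales$scale_max,
                 as.integer(neutral_value))
  out <- tibble::as_tibble(as.list(setNames(as.integer(vals),
                                            paste0("v", scales$variable))))
  dplyr::bind_cols(tibble::tibble(nodule_id = "pattern"), out)
}

# sign array S[p, l, j] = sgn(x[p, j] - x[l, j]) for a data matrix x
gdm2_signs <- function(x) {
  n <- nrow(x); p <- ncol(x)
  s <- array(0, dim = c(n, n, p))
  for (j in seq_len(p)) {
    s[, , j] <- sign(outer(x[, j], x[, j], `-`))
  }
  s
}

#' GDM2 distance between two objects of a context set
#'
#' Context-dependent by design: the distance between rows `i` and `k`
#' involves sign comparisons against **every** row of `x`, so adding or
#' removing other objects changes d_ik. Both the fully tied degenerate
#' case (identical profiles in an all-tied context, d = 0) and the
#' inadmissible one (zero denominator with distinct profiles) are handled
#' explicitly.
#'
#' @param x Numeric matrix, one row per object (the full context set).
#' @param i,k Row indices of the two objects.
#' @param weights Positive variable weights (recycled to `ncol(x)`).
#' @return Distance in \[0, 1\].
#' @export
gdm2_distance <- function(x, i, k, weights = rep(1, ncol(x))) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("context must hold at least two objects")
  if (any(weights <= 0)) abort("weights must be positive")
  w <- rep_len(weights, ncol(x))
  s <- gdm2_signs(x)
  gdm2_from_signs(s, i, k, w, x)
}

# core evaluation from a precomputed sign array; `ctx` is the index set of
# objects forming the context (the l-sums range over it)
gdm2_from_signs <- function(s, i, k, w, x, ctx = seq_len(dim(s)[1])) {
  others <- setdiff(ctx, c(i, k))
  wsum <- function(p, drop_set) {
    ll <- setdiff(ctx, drop_set)
    m <- matrix(s[p, ll, ], nrow = length(ll))
    sum(sweep(m^2, 2, w, `*`))
  }
  # term over the pair itself: a_ikj * b_kij
  t1 <- sum(w * s[i, k, ] * s[k, i, ])
  # cross terms over the rest of the context
  t2 <- if (length(others) > 0) {
    si <- matrix(s[i, others, ], nrow = length(others))
    sk <- matrix(s[k, others, ], nrow = length(others))
    sum(sweep(si * sk, 2, w, `*`))
  } else 0
  den <- 2 * sqrt(wsum(i, i) * wsum(k, k))
  if (den == 0) {
    if (all(x[i, ] == x[k, ])) return(0)
    abort("degenerate GDM2 context: zero denominator for distinct profiles")
  }
  d <- 0.5 - (t1 + t2) / den
  # guard against floating-point excursions just outside [0, 1]
  min(max(d, 0), 1)
}

#' All pairwise GDM2 distances of a context set
#'
#' @inheritParams gdm2_distance
#' @return Symmetric n x n matrix of distances.
#' @export
gdm2_pairwise <- function(x, weights = rep(1, ncol(x))) {
  x <- as.matrix(x)
  w <- rep_len(weights, ncol(x))
  s <- gdm2_signs(x)
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      d[i, k] <- d[k, i] <- gdm2_from_signs(s, i, k, w, x)
    }
  }
  d
}

#' Synthetic variable: GDM2 distance of each nodule from the pattern
#'
#' Appends the pattern object to the cohort (the context set is the
#' analysed cohort plus the pattern, nothing else) and computes each
#' record's GDM2 distance to it. Distance 0 means identical to the ideal
#' malignant-like profile; ascending distance orders nodules from most to
#' least malignant-like. The distance of a record does not depend on the
#' input order of the cohort.
#'
#' @param records Tibble of feature records with columns v1..v4 (scores on
#'   the ordinal scales).
#' @param scales A [scale_specs()] tibble.
#' @param neutral_value Pattern value for neutral variables (default 2).
#' @param include_pattern Keep the pattern object in the context set
#'   (default TRUE).
#' @return `records` with a `distance` column appended.
#' @export
synthetic_variable <- function(records, scales = scale_specs(),
                               neutral_value = 2L, include_pattern = TRUE) {
  if (nrow(records) == 0) abort("cohort is empty")
  validate_feature_scores(records, where = "cohort")
  pat <- pattern_object(scales, neutral_value)
  vars <- paste0("v", scales$variable)
  x <- as.matrix(rbind(records[vars], pat[vars]))
  n <- nrow(records)
  s <- gdm2_signs(x)
  ctx_pat <- n + 1L
  # with the pattern in the context the l-sums run over cohort + pattern;
  # without it they run over the cohort only and the pattern serves purely
  # as the comparison endpoint
  ctx <- if (include_pattern) seq_len(n + 1L) else seq_len(n)
  d <- vapply(seq_len(n), function(i) {
    gdm2_from_signs(s, i, ctx_pat, scales$weight, x, ctx = ctx)
  }, 0)
  dplyr::mutate(records, distance = d)
}

#' Segment a sorted synthetic variable by the maximum-gradient method
#'
#' Finds the three largest differences between subsequent values of the
#' sorted synthetic variable; the boundary values are the midpoints of
#' those gaps and split the cohort into four contiguous groups I-IV from
#' smallest distance (most malignant-like) upward. Ties between equal gaps
#' are broken toward the smaller index.
#'
#' @param distances Numeric vector of synthetic-variable values (any
#'   order; at least 4 distinct values required).
#' @return List: `boundaries` (3 increasing values) and `group` (ordered
#'   factor I-IV aligned with `distances`).
#' @export
max_gradient_groups <- function(distances) {
  if (length(distances) < 4 || length(unique(distances)) < 4) {
    abort("maximum-gradient grouping needs at least 4 distinct values")
  }
  s <- sort(distances)
  gaps <- diff(s)
  pick <- order(-gaps, seq_along(gaps))[1:3]
  boundaries <- sort((s[pick] + s[pick + 1L]) / 2)
  group <- factor(c("I", "II", "III", "IV")[1L + findInterval(distances, boundaries)],
                  levels = c("I", "II", "III", "IV"), ordered = TRUE)
  list(boundaries = boundaries, group = group)
}

#' Classify nodules at the synthetic-variable decision threshold
#'
#' A distance from the pattern object at or below the threshold (default
#' 0.4, boundary inclusive) indicates distinct features of malignancy;
#' above it, benignity can be expected.
#'
#' @param distances Numeric vector of synthetic-variable values.
#' @param threshold Decision threshold (default 0.4).
#' @return Character vector "malignant"/"benign" of expected labels.
#' @export
classify_nodules <- function(distances, threshold = 0.4) {
  ifelse(distances <= threshold, "malignant", "benign")
}

#' Summary statistics of the group compositions
#'
#' From the per-group counts of truly malignant and benign nodules:
#' the fraction confidently classified (groups I and IV), the
#' indeterminate fraction (II and III), the accuracy of the
#' threshold rule (malignant nodules falling in groups I or II over all
#' malignant), and each group's share of its label class. Percentages are
#' reported both raw and rounded to one decimal, half away from zero.
#'
#' @param compositions Tibble/data frame with columns `group` (I-IV),
#'   `n_malignant`, `n_benign`.
#' @return List of summary percentages and the per-group share table.
#' @export
summarize_groups <- function(compositions) {
  cmp <- dplyr::arrange(tibble::as_tibble(compositions), .data$group)
  if (!all(c("I", "II", "III", "IV") %in% as.character(cmp$group))) {
    abort("`compositions` must cover groups I-IV")
  }
  tot <- sum(cmp$n_malignant) + sum(cmp$n_benign)
  if (tot == 0) abort("empty composition table")
  n_mal <- sum(cmp$n_malignant)
  n_ben <- sum(cmp$n_benign)
  grp <- function(g) cmp[as.character(cmp$group) == g, ]
  confident <- (sum(grp("I")$n_malignant + grp("I")$n_benign) +
                  sum(grp("IV")$n_malignant + grp("IV")$n_benign)) / tot * 100
  indeterminate <- 100 - confident
  acc <- if (n_mal > 0) {
    (grp("I")$n_malignant + grp("II")$n_malignant) / n_mal * 100
  } else NA_real_
  shares <- dplyr::mutate(
    cmp,
    malignant_share_pct = if (n_mal > 0) .data$n_malignant / n_mal * 100 else
      NA_real_,
    benign_share_pct = if (n_ben > 0) .data$n_benign / n_ben * 100 else
      NA_real_)
  list(
    n = tot,
    pct_confident = confident,
    pct_indeterminate = indeterminate,
    accuracy_at_threshold = acc,
    shares = shares,
    rounded = list(
      pct_confident = round_half_away(confident, 1),
      pct_indeterminate = round_half_away(indeterminate, 1),
      accuracy_at_threshold = round_half_away(acc, 1),
      malignant_share_pct = round_half_away(shares$malignant_share_pct, 1),
      benign_share_pct = round_half_away(shares$benign_share_pct, 1)))
}
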