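#' Rank a cohort of nodules by the GDM2 synthetic variable
#'
#' The full analysis stage: computes each record's GDM2 distance from the
#' pattern object, orders the cohort ascending (most malignant-like
#' first), segments the ordering with the maximum-gradient method into
#' groups I-IV, and classifies every nodule at the decision threshold.
#' With fewer than four distinct distances the grouping is skipped with a
#' warning and distances/classifications are still returned.
#'
#' @param records Tibble of feature records (columns `nodule_id`,
#'   `v1`..`v4`, optional `label`).
#' @param scales A [scale_specs()] tibble.
#' @param threshold Decision threshold on the distance (default 0.4).
#' @param neutral_value Pattern value for neutral variables.
#' @param include_pattern Keep the pattern object in the GDM2 context.
#' @return A `nodule_ranking` object; see [tidy.nodule_ranking()].
#' @export
rank_cohort <- function(records, scales = scale_specs(), threshold = 0.4,
                        neutral_value = 2L, include_pattern = TRUE) {
  scored <- synthetic_variable(records, scales, neutral_value,
                               include_pattern)
  scored$expected_label <- classify_nodules(scored$distance, threshold)
  groups <- tryCatch(max_gradient_groups(scored$distance),
                     error = function(e) {
                       warn(conditionMessage(e))
                       NULL
                     })
  scored$group <- if (is.null(groups)) {
    factor(rep(NA_character_, nrow(scored)),
           levels = c("I", "II", "III", "IV"), ordered = TRUE)
  } else {
    groups$group
  }
  scored <- dplyr::arrange(scored, .data$distance)
  scored$rank <- seq_len(nrow(scored))
  structure(
    list(records = scored,
         boundaries = if (is.null(groups)) NULL else groups$boundaries,
         threshold = threshold,
         scales = scales,
         pattern = pattern_object(scales, neutral_value),
         include_pattern = include_pattern),
    class = "nodule_ranking")
}

#' @export
print.nodule_ranking <- function(x, ...) {
  cat(sprintf("<nodule_ranking> %d nodules, threshold %.2f\n",
              nrow(x$records), x$threshold))
  if (!is.null(x$boundaries)) {
    cat(sprintf("  group boundaries: %s\n",
                paste(sprintf("%.3f", x$boundaries), collapse = ", ")))
  }
  print(utils::head(tidy(x), 5))
  invisible(x)
}

#' Tidy a nodule ranking
#'
#' @param x A `nodule_ranking`.
#' @param ... Unused.
#' @return Tibble with one row per nodule: scores, `distance`, `rank`,
#'   `group`, `expected_label` (ascending distance order).
#' @method tidy nodule_ranking
#' @export
tidy.nodule_ranking <- function(x, ...) {
  dplyr::relocate(x$records, "nodule_id", "rank", "distance", "group",
                  "expected_label")
}

#' One-row summary of a nodule ranking
#'
#' @param x A `nodule_ranking`.
#' @param ... Unused.
#' @return Tibble with the cohort size, the three group boundaries, the
#'   confident/indeterminate percentages and (when true labels are
#'   present) the threshold-rule accuracy.
#' @method glance nodule_ranking
#' @export
glance.nodule_ranking <- function(x, ...) {
  out <- tibble::tibble(
    n = nrow(x$records),
    boundary_1 = x$boundaries[1] %||% NA_real_,
    boundary_2 = x$boundaries[2] %||% NA_real_,
    boundary_3 = x$boundaries[3] %||% NA_real_,
    threshold = x$threshold)
  comp <- ranking_compositions(x)
  if (!is.null(comp)) {
    sm <- summarize_groups(comp)
    out$pct_confident <- sm$pct_confident
    out$pct_indeterminate <- sm$pct_indeterminate
    out$accuracy_at_threshold <- sm$accuracy_at_threshold
  }
  out
}

# group compositions (true-label counts per group), or NULL when labels or
# groups are unavailable
ranking_compositions <- function(x) {
  rec <- x$records
  if (is.null(x$boundaries) || !"label" %in% names(rec) ||
      all(is.na(rec$label))) {
    return(NULL)
  }
  tibble::tibble(
    group = factor(c("I", "II", "III", "IV"),
                   levels = c("I", "II", "III", "IV"), ordered = TRUE),
    n_malignant = vapply(c("I", "II", "III", "IV"), function(g)
      sum(rec$group == g & rec$label == "malignant", na.rm = TRUE), 0L),
    n_benign = vapply(c("I", "II", "III", "IV"), function(g)
      sum(rec$group == g & rec$label == "benign", na.rm = TRUE), 0L))
}

#' Plot the linear ordering of the synthetic variable
#'
#' Nodules in ascending distance from the pattern object, with the
#' maximum-gradient group boundaries (dashed) and the decision threshold
#' (dotted).
#'
#' @param object A `nodule_ranking`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nodule_ranking
#' @export
autoplot.nodule_ranking <- function(object, ...) {
  rec <- tidy(object)
  p <- ggplot2::ggplot(rec, ggplot2::aes(x = .data$rank, y = .data$distance)) +
    ggplot2::geom_point(ggplot2::aes(
      shape = if ("label" %in% names(rec) && !all(is.na(rec$label)))
        .data$label else NULL)) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dotted") +
    ggplot2::labs(x = "nodule (sorted)", y = "GDM2 distance from pattern",
                  shape = "label") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(object$boundaries)) {
    p <- p + ggplot2::geom_hline(yintercept = object$boundaries,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Write the ranking CSV and summary JSON of an analysis
#'
#' @param ranking A `nodule_ranking`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @param config Optional resolved configuration echoed into the JSON.
#' @return Invisibly, the summary list written to JSON.
#' @export
write_ranking <- function(ranking, csv_path = NULL, json_path = NULL,
                          config = NULL) {
  td <- tidy(ranking)
  if (!is.null(csv_path)) {
    readr::write_csv(td, csv_path)
  }
  comp <- ranking_compositions(ranking)
  summary <- list(
    n = nrow(td),
    boundaries = ranking$boundaries,
    threshold = ranking$threshold,
    groups = as.list(table(td$group)),
    compositions = comp,
    summary = if (!is.null(comp)) {
      sm <- summarize_groups(comp)
      sm[c("pct_confident", "pct_indeterminate", "accuracy_at_threshold")]
    },
    config = config)
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", force = TRUE)
  }
  invisible(summary)
}
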