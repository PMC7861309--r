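#' Plot a substitute ranking
#'
#' Horizontal bars of DIISH scores, best candidate on top.
#'
#' @param object A `ranked_list` from [rank_substitutes()].
#' @param top Number of candidates to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ranked_list <- function(object, top = 10, ...) {
  df <- utils::head(tibble::as_tibble(object), top)
  df$candidate_id <- stats::reorder(df$candidate_id, df$score)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$candidate_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "DIISH score", y = NULL,
      title = paste0("Substitutes for '", attr(object, "target"), "'")
    ) +
    ggplot2::theme_minimal()
}

#' Plot ranking-evaluation metrics
#'
#' One bar per aggregate metric (MAP, MRR, and each recall-rate cutoff).
#'
#' @param object A `ranking_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ranking_report <- function(object, ...) {
  df <- tibble::tibble(
    metric = factor(
      c("MAP", "MRR", names(object$RR_at)),
      levels = c("MAP", "MRR", names(object$RR_at))
    ),
    value = c(object$MAP, object$MRR, unname(object$RR_at))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "value", title = "Ranking evaluation") +
    ggplot2::theme_minimal()
}

#' Plot per-ingredient nutrient contributions
#'
#' @param object A `nutrient_breakdown`.
#' @param nutrient Nutrient to display; defaults to the first in the
#'   totals.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.nutrient_breakdown <- function(object, nutrient = NULL, ...) {
  nutrient <- nutrient %||% names(object$recipe_totals)[[1]]
  df <- top_contributors(object, nutrient)
  df$ingredient_id <- stats::reorder(df$ingredient_id, df$amount)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$amount, y = .data$ingredient_id)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::labs(
      x = paste0(nutrient, " contributed"), y = NULL,
      title = paste0("Recipe '", object$recipe_id, "'")
    ) +
    ggplot2::theme_minimal()
}
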