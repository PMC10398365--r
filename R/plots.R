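#' Plot an occurrence-frequency profile
#'
#' Bar chart of per-category occurrence frequencies, one panel colour per
#' forum, categories in lexicon order.
#'
#' @param object A [corpus_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cessalex_profile
#' @export
autoplot.cessalex_profile <- function(object, ...) {
  cats <- attr(object, "categories")
  df <- dplyr::mutate(as_tibble(object),
                      category = factor(.data$category, levels = cats))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$frequency,
                                   fill = .data$forum)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "occurrence frequency (%)",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a cosine-similarity heatmap
#'
#' @param object A [similarity_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cessalex_simmat
#' @export
autoplot.cessalex_simmat <- function(object, ...) {
  df <- tidy(object)
  ord <- rownames(object)
  df$forum_a <- factor(df$forum_a, levels = ord)
  df$forum_b <- factor(df$forum_b, levels = rev(ord))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$forum_a, y = .data$forum_b,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "cosine") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
}

#' Plot binned emotion trajectories over abstinence duration
#'
#' Occurrence frequency per abstinence bin, optionally restricted to a
#' category subset, on a log-scaled day axis (bin midpoints).
#'
#' @param object A [bin_posts()] table.
#' @param categories Categories to show; default all.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cessalex_binned
#' @export
autoplot.cessalex_binned <- function(object, categories = NULL, ...) {
  bins <- attr(object, "bins")
  mid <- exp((log(pmax(bins$lower, 0.5)) + log(bins$upper)) / 2)
  df <- as_tibble(object)
  df$day <- mid[df$bin]
  if (!is.null(categories)) {
    df <- dplyr::filter(df, .data$category %in% categories)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$frequency,
                                   colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$level)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "abstinence duration (days)",
                  y = "occurrence frequency (%)",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}
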