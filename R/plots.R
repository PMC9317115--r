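#' Plot a top-neighbors result table
#'
#' Correlation of each returned partner against its significance rank, signed
#' so positive and negative correlates separate visually.
#'
#' @param neighbors Tibble from [top_neighbors()].
#' @return A ggplot object.
#' @export
plot_neighbors <- function(neighbors) {
  stopifnot(all(c("partner", "r", "p_raw") %in% names(neighbors)))
  df <- dplyr::mutate(neighbors, rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$r,
                                   colour = .data$r > 0)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::labs(x = "rank by raw p-value", y = "Pearson r",
                  title = if (nrow(df) > 0)
                    sprintf("Top %d correlates of %s", nrow(df), df$seed[1])
                  else "Top correlates")
}
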