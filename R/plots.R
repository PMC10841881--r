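#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_boxplot
#'   labs scale_fill_manual theme_minimal
#' @export
ggplot2::autoplot

CATEGORY_FILLS <- c(Acceptable = "#8da0cb", Medium = "#fc8d62",
                    High = "#66c2a5")

#' Stacked category contributions of a group ranking
#'
#' One bar per group, ordered by rank; bar segments show the CAPRI-score
#' contribution of acceptable, medium and high-quality assessment units
#' (weights 1, 2, 3).
#'
#' @param object a `capri_ranking` from [rank_groups()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot capri_ranking
#' @export
autoplot.capri_ranking <- function(object, ...) {
  w <- attr(object, "weights")
  df <- tidy(object) |>
    tidyr::pivot_longer(c("n_acc", "n_med", "n_high"),
                        names_to = "quality", values_to = "n") |>
    mutate(
      quality = dplyr::recode(.data$quality, n_acc = "Acceptable",
                              n_med = "Medium", n_high = "High"),
      contribution = .data$n * w[.data$quality],
      quality = factor(.data$quality,
                       levels = c("High", "Medium", "Acceptable")))
  ggplot(df, aes(x = stats::reorder(.data$group_id, .data$capri_rank),
                 y = .data$contribution, fill = .data$quality)) +
    geom_col() +
    scale_fill_manual(values = CATEGORY_FILLS) +
    labs(x = NULL, y = "CAPRI score contribution", fill = NULL) +
    theme_minimal()
}

#' DockQ distribution of a decoy ladder by category
#'
#' @param truth the `truth` tibble of [make_decoy_ladder()].
#' @return A ggplot (boxplot of DockQ per intended category).
#' @export
plot_decoy_ladder <- function(truth) {
  df <- mutate(truth, intended = factor(.data$intended,
                                        levels = CATEGORY_LEVELS))
  ggplot(df, aes(x = .data$intended, y = .data$dockq)) +
    geom_boxplot(outlier.shape = NA) +
    geom_point(aes(colour = .data$category)) +
    labs(x = "intended category", y = "DockQ", colour = "oracle label") +
    theme_minimal()
}
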