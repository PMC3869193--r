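# Standard figures: normalized growth curves per droplet colored by
# loading concentration, and box plots of threshold growth time per
# concentration.

#' Plot normalized growth curves
#'
#' @param series Series tibble with a `normalized` column (see
#'   [normalize_curve()]); one line per droplet.
#' @param groups Optional tibble (`droplet_id`, `group`) to color lines.
#' @param threshold Reference level drawn as a dashed line (default 0.99).
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(series, groups = NULL, threshold = 0.99) {
  stopifnot(is.data.frame(series), "normalized" %in% names(series))
  df <- series
  df$group <- if (!is.null(groups))
    factor(groups$group[match(df$droplet_id, groups$droplet_id)])
  else factor("all")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$normalized,
                                   group = .data$droplet_id,
                                   colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.4, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "time (h)", y = "normalized transmission",
                  colour = "cells/droplet") +
    ggplot2::theme_minimal()
}

#' Box plots of threshold growth time per group
#'
#' @param results Growth-results tibble (see [analyze_droplets()]).
#' @return A ggplot object.
#' @export
plot_threshold_boxes <- function(results) {
  df <- results[results$grew & !is.na(results$threshold_time_h), ]
  if (nrow(df) == 0L)
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "no grown droplets"))
  df$group <- factor(df$group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group,
                                   y = .data$threshold_time_h)) +
    ggplot2::geom_boxplot(coef = 1.5, fill = "grey85") +
    ggplot2::labs(x = "cells per droplet (nominal)",
                  y = "threshold growth time (h)") +
    ggplot2::theme_minimal()
}
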