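# ggplot2 graphics for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a resistance-evolution trajectory
#'
#' Resistance allele frequencies at both loci and the population's fitness on
#' the deployed transgenic cotton, against time in years. The dashed line
#' marks the resistance threshold.
#'
#' @param object A `resistance_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.resistance_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$trajectory,
    cols = c("p1", "p2", "pop_fitness"),
    names_to = "series", values_to = "value"
  ) |>
    dplyr::mutate(series = dplyr::recode(
      .data$series,
      p1 = "Bt resistance allele freq",
      p2 = "RNAi resistance allele freq",
      pop_fitness = "Population fitness on transgenic cotton"
    ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = object$scenario$resistance_threshold,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      title = sprintf("%s, %s, %g%% refuge", object$scenario$name,
                      object$strategy, 100 * object$scenario$refuge_fraction),
      x = "Years", y = "Frequency / fitness", colour = NULL
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot a durability table
#'
#' Years to resistance against refuge percentage, one line per deployment
#' strategy, faceted by scenario — the standard way to compare how long each
#' deployment lasts as refuge size varies.
#'
#' @param sweep_tbl Output of [refuge_sweep()].
#' @return A ggplot.
#' @export
plot_durability <- function(sweep_tbl) {
  ggplot2::ggplot(sweep_tbl,
                  ggplot2::aes(x = 100 * .data$refuge,
                               y = .data$years_to_resistance,
                               colour = .data$strategy)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~ .data$scenario) +
    ggplot2::labs(x = "Refuge (%)", y = "Years to resistance",
                  colour = "Strategy") +
    ggplot2::theme_minimal()
}

#' Plot bioassay mortality by cotton type
#'
#' Replicate-level mortality with per-cell means, in the layout of a
#' mortality bar figure: cotton type on the x axis, strains side by side,
#' faceted by year.
#'
#' @param data Bioassay tibble.
#' @return A ggplot.
#' @export
plot_mortality <- function(data) {
  d <- summarize_bioassay(data)
  d$cotton <- factor(d$cotton, levels = unique(d$cotton))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cotton, y = .data$mortality_pct,
                                  fill = .data$strain)) +
    ggplot2::stat_summary(fun = mean, geom = "col",
                          position = ggplot2::position_dodge(width = 0.8),
                          width = 0.7) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.8),
                        shape = 21, colour = "black", size = 1.6) +
    ggplot2::facet_wrap(~ .data$year) +
    ggplot2::labs(x = NULL, y = "Mortality (%)", fill = "Strain") +
    ggplot2::theme_minimal()
}
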