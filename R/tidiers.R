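# broom-style tidiers for the package's fitted/result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a resistance simulation
#'
#' @param x A `resistance_sim` from [time_to_resistance()].
#' @param ... Unused.
#' @return The per-generation trajectory tibble: `generation`, `year`, `p1`,
#'   `p2`, `D`, `pop_fitness`.
#' @export
tidy.resistance_sim <- function(x, ...) {
  x$trajectory
}

#' @rdname tidy.resistance_sim
#' @return `glance()` returns a one-row summary: scenario, strategy, refuge,
#'   `years_to_resistance`, `reached`, generations simulated and final allele
#'   frequencies.
#' @export
glance.resistance_sim <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  tibble::tibble(
    scenario = x$scenario$name, strategy = x$strategy,
    refuge = x$scenario$refuge_fraction,
    years_to_resistance = x$years_to_resistance, reached = x$reached,
    generations = last$generation, final_p1 = last$p1, final_p2 = last$p2,
    final_pop_fitness = last$pop_fitness
  )
}

#' Tidy an IMS result
#'
#' @param x An `ims_result` from [ims()].
#' @param ... Unused.
#' @return The per-replicate table of adjusted survivals and IMS values.
#' @export
tidy.ims_result <- function(x, ...) {
  x$per_replicate
}

#' @rdname tidy.ims_result
#' @return `glance()` returns the one-row pooled test: `ims`, `se`, `n`,
#'   `t_stat`, `df`, `p_value`.
#' @export
glance.ims_result <- function(x, ...) {
  tibble::tibble(strain = x$strain, ims = x$ims, se = x$se, n = x$n,
                 t_stat = x$t_stat, df = x$df, p_value = x$p_value)
}

#' Tidy a one-way comparison
#'
#' @param x A `oneway_comparison` from [compare_groups_oneway()].
#' @param ... Unused.
#' @return The pairwise Tukey HSD table.
#' @export
tidy.oneway_comparison <- function(x, ...) {
  x$tukey
}

#' @rdname tidy.oneway_comparison
#' @return `glance()` returns the one-row ANOVA summary: `df`, `df_residual`,
#'   `statistic`, `p_value`.
#' @export
glance.oneway_comparison <- function(x, ...) {
  tibble::tibble(
    df = x$anova$df[1], df_residual = x$anova$df[2],
    statistic = x$anova$statistic[1], p_value = x$anova$p_value[1]
  )
}
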