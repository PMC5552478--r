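# Group comparisons: one-way ANOVA with Tukey HSD and compact letters,
# strain t-tests, and two-way ANOVA for the year x pyramid design.

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Fits a one-way ANOVA of `value` on `group`, runs Tukey's honestly
#' significant difference test on all pairwise contrasts, and assigns compact
#' letters: groups sharing a letter do not differ significantly at `alpha`.
#' Letters are assigned greedily from the largest group mean downwards — each
#' group joins every existing letter class whose members it does not differ
#' from, and opens a new letter otherwise.
#'
#' @param data Data frame with at least the two analysis columns.
#' @param value,group Column names (strings) of the response and the grouping
#'   factor.
#' @param alpha Significance level for the letter display.
#' @return A `oneway_comparison` with elements `anova` (tibble: term, df,
#'   sumsq, meansq, statistic, p_value), `tukey` (tibble of pairwise
#'   contrasts) and `letters` (tibble: group, mean, n, letters). `tidy()`
#'   returns the Tukey table, `glance()` the one-row ANOVA summary.
#' @examples
#' d <- data.frame(g = rep(c("W0", "GFP", "Bt"), each = 3),
#'                 y = c(10, 11, 12, 10, 12, 11, 30, 32, 31))
#' compare_groups_oneway(d, "y", "g")$letters
#' @export
compare_groups_oneway <- function(data, value, group, alpha = 0.05) {
  y <- data[[value]]
  g <- factor(data[[group]], levels = unique(data[[group]]))
  if (nlevels(g) < 2) stop("Need at least 2 groups.", call. = FALSE)
  if (any(table(g) < 2)) stop("Need at least 2 values per group.", call. = FALSE)
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  anova_tbl <- tibble::tibble(
    term = c(group, "Residuals"),
    df = an$Df, sumsq = an$`Sum Sq`, meansq = an$`Mean Sq`,
    statistic = an$`F value`, p_value = an$`Pr(>F)`
  ) |> zero_ss_is_zero_f()
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey_tbl <- tibble::tibble(
    group1 = vapply(pair, `[`, character(1), 1),
    group2 = vapply(pair, `[`, character(1), 2),
    estimate = tk[, "diff"], conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  means <- tapply(y, g, mean)
  letters_tbl <- tibble::tibble(
    group = names(means), mean = as.numeric(means),
    n = as.integer(table(g)[names(means)])
  )
  letters_tbl$letters <- compact_letters(letters_tbl$group, letters_tbl$mean,
                                         tukey_tbl, alpha)
  letters_tbl <- dplyr::arrange(letters_tbl, dplyr::desc(.data$mean))
  structure(list(anova = anova_tbl, tukey = tukey_tbl, letters = letters_tbl,
                 alpha = alpha, value = value, group = group),
            class = "oneway_comparison")
}

# Greedy letter assignment from the largest mean down. Ties in mean keep the
# group factor order.
compact_letters <- function(groups, means, tukey_tbl, alpha) {
  ord <- order(-means)
  p_of <- function(a, b) {
    hit <- (tukey_tbl$group1 == a & tukey_tbl$group2 == b) |
      (tukey_tbl$group1 == b & tukey_tbl$group2 == a)
    p <- tukey_tbl$p_adj[hit][1]
    # NaN arises with zero residual variance and a zero contrast: no evidence
    # of a difference, so treat as non-significant.
    if (is.na(p)) 1 else p
  }
  classes <- list()  # each element: character vector of member groups
  for (gr in groups[ord]) {
    joined <- FALSE
    for (k in seq_along(classes)) {
      if (all(vapply(classes[[k]], function(m) p_of(gr, m) >= alpha, logical(1)))) {
        classes[[k]] <- c(classes[[k]], gr)
        joined <- TRUE
      }
    }
    if (!joined) classes[[length(classes) + 1]] <- gr
  }
  lab <- letters[seq_along(classes)]
  vapply(groups, function(gr) {
    paste(lab[vapply(classes, function(cl) gr %in% cl, logical(1))],
          collapse = "")
  }, character(1))
}

#' @export
print.oneway_comparison <- function(x, ...) {
  a <- x$anova[1, ]
  cat(sprintf("<oneway_comparison> %s ~ %s: F(%d, %d) = %.3g, P = %.3g\n",
              x$value, x$group, a$df, x$anova$df[2], a$statistic, a$p_value))
  print(as.data.frame(x$letters), row.names = FALSE)
  invisible(x)
}

#' Two-sample t-test between strains
#'
#' Tests the null hypothesis of no difference between two strains (e.g.
#' resistant vs. susceptible) in a response such as mortality or development
#' time. Welch's unequal-variance test is the default, robust with the small
#' replicate numbers typical of leaf bioassays; set `var_equal = TRUE` for the
#' pooled-variance variant. When both samples are degenerate (zero variance)
#' with equal means, `p_value = 1` is returned with a message rather than an
#' error.
#'
#' @param values_a,values_b Numeric vectors (>= 2 values each).
#' @param var_equal Use the pooled-variance test?
#' @return Tibble with `estimate` (mean difference a - b), `statistic`, `df`,
#'   `p_value`, `method`.
#' @export
compare_strains_ttest <- function(values_a, values_b, var_equal = FALSE) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    same <- mean(values_a) == mean(values_b)
    message("Degenerate variance in both samples; p = ",
            if (same) "1 (equal means)." else "0 (means differ with no variance).")
    return(tibble::tibble(
      estimate = mean(values_a) - mean(values_b),
      statistic = if (same) 0 else Inf, df = NA_real_,
      p_value = if (same) 1 else 0,
      method = "degenerate"
    ))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  tibble::tibble(
    estimate = mean(values_a) - mean(values_b),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, method = tt$method
  )
}

#' Two-way ANOVA for a factorial bioassay design
#'
#' Fits `response ~ factor_a * factor_b` (main effects plus interaction), as
#' in testing for effects of year, type of pyramid and their interaction on
#' mortality or development time. The design must be complete: every
#' factor-level combination needs at least one replicate.
#'
#' @param data Data frame.
#' @param response,factor_a,factor_b Column names (strings).
#' @return Tidy ANOVA tibble: `term`, `df`, `sumsq`, `meansq`, `statistic`,
#'   `p_value`.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  y <- data[[response]]
  a <- factor(data[[factor_a]])
  b <- factor(data[[factor_b]])
  if (any(table(a, b) == 0)) {
    stop("Incomplete design: every ", factor_a, " x ", factor_b,
         " cell needs at least one observation.", call. = FALSE)
  }
  fit <- stats::aov(y ~ a * b)
  an <- summary(fit)[[1]]
  tibble::tibble(
    term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b), "Residuals"),
    df = an$Df, sumsq = an$`Sum Sq`, meansq = an$`Mean Sq`,
    statistic = an$`F value`, p_value = an$`Pr(>F)`
  ) |> zero_ss_is_zero_f()
}

# An effect that explains (numerically) zero sum of squares has F = 0 and
# p = 1 by convention, even when the residual mean square is also zero
# (constant data), where R's aov would report 0/0 = NaN. "Zero" is judged
# relative to the total sum of squares to absorb floating-point dust.
zero_ss_is_zero_f <- function(tbl) {
  thresh <- 1e-12 * sum(tbl$sumsq) + 1e-25
  eff <- tbl$term != "Residuals" & tbl$sumsq < thresh
  tbl$statistic[eff] <- 0
  tbl$p_value[eff] <- 1
  tbl
}
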