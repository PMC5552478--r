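# Cotton leaf bioassay statistics.
#
# A bioassay data frame holds one replicate per row: strain, cotton, year,
# replicate, n_larvae, n_normal_pupae, and optionally dev_times_days (per
# normal pupa, as a list-column or a semicolon-joined string). Survival is the
# proportion of larvae that became normal pupae; malformed pupae count as
# dead.

#' Read / write bioassay records
#'
#' Reads a delimited file (comma or tab, auto-detected from the extension)
#' with one bioassay replicate per row. A `dev_times_days` column, if present,
#' may be a semicolon-joined list of per-survivor days to pupation; it is
#' parsed into a list-column.
#'
#' @param path File path (`.csv` or `.tsv`).
#' @return A tibble of bioassay records.
#' @export
read_bioassay <- function(path) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  x <- reader(path, show_col_types = FALSE)
  validate_bioassay(x)
  if ("dev_times_days" %in% names(x) && is.character(x$dev_times_days)) {
    x$dev_times_days <- lapply(x$dev_times_days, function(s) {
      if (is.na(s) || !nzchar(s)) return(numeric(0))  # zero survivors
      as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }
  tibble::as_tibble(x)
}

#' @rdname read_bioassay
#' @param x Bioassay tibble (list-column `dev_times_days` is flattened back to
#'   a semicolon-joined string).
#' @export
write_bioassay <- function(x, path) {
  validate_bioassay(x)
  if ("dev_times_days" %in% names(x) && is.list(x$dev_times_days)) {
    x$dev_times_days <- vapply(x$dev_times_days, paste, character(1),
                               collapse = ";")
  }
  writer <- if (grepl("\\.tsv$", path)) readr::write_tsv else readr::write_csv
  writer(x, path)
  invisible(path)
}

validate_bioassay <- function(x) {
  need <- c("strain", "cotton", "year", "replicate", "n_larvae", "n_normal_pupae")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("Bioassay data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(x$n_normal_pupae > x$n_larvae | x$n_normal_pupae < 0 |
                 x$n_larvae <= 0)
  if (length(bad)) {
    stop("Invalid counts in bioassay row(s) ", paste(bad, collapse = ", "),
         ": need 0 <= n_normal_pupae <= n_larvae and n_larvae > 0.",
         call. = FALSE)
  }
  invisible(x)
}

#' Per-replicate survival, mortality and development time
#'
#' Survival is the proportion of larvae that became normal pupae (malformed
#' pupae are not survivors); mortality (%) is `100 * (1 - survival)`.
#' Development time is the mean days from hatching to pupation among normal
#' pupae in the replicate.
#'
#' @param data Bioassay tibble (see [read_bioassay()]).
#' @return The input with added columns `survival`, `mortality_pct` and, when
#'   development times are present, `dev_time_mean`.
#' @examples
#' d <- tibble::tibble(strain = "SCD", cotton = "Bt+JHA", year = "2016",
#'                     replicate = 1, n_larvae = 50, n_normal_pupae = 4)
#' summarize_bioassay(d)$mortality_pct  # 92
#' @export
summarize_bioassay <- function(data) {
  validate_bioassay(data)
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    survival = .data$n_normal_pupae / .data$n_larvae,
    mortality_pct = 100 * (1 - .data$survival)
  )
  if ("dev_times_days" %in% names(out)) {
    out$dev_time_mean <- vapply(out$dev_times_days, function(v) {
      if (length(v) == 0) NA_real_ else mean(v)
    }, numeric(1))
  }
  out
}

#' Transgene efficacy
#'
#' Efficacy (%) is `100 * (1 - survival_transgenic / survival_control)`.
#' Negative values (better survival on the transgenic cotton than on the
#' control) are reported as computed, not clipped.
#'
#' @param survival_transgenic,survival_control Survival proportions
#'   (vectorized).
#' @return Efficacy percentage(s).
#' @examples
#' efficacy_pct(0.08, 0.84)  # 90.5 to 1 d.p.
#' @export
efficacy_pct <- function(survival_transgenic, survival_control) {
  if (any(survival_control <= 0)) {
    stop("Efficacy is undefined when control survival is zero.", call. = FALSE)
  }
  100 * (1 - survival_transgenic / survival_control)
}

#' Efficacy of each transgenic cotton from bioassay data
#'
#' For each strain x year, pools the replicates of every transgenic cotton
#' type and of the non-transgenic control, and reports the efficacy of the
#' transgenic cotton against that strain.
#'
#' @param data Bioassay tibble.
#' @param control Label of the non-transgenic control cotton (default `"W0"`,
#'   the untransformed parent).
#' @param exclude Cotton labels that are neither the control nor a transgenic
#'   treatment of interest (default `"GFP"`, the transgenic empty-vector
#'   control).
#' @return Tibble with columns `strain`, `year`, `cotton`,
#'   `survival_transgenic`, `survival_control`, `efficacy_pct`.
#' @export
bioassay_efficacy <- function(data, control = "W0", exclude = "GFP") {
  data <- summarize_bioassay(data)
  if (!control %in% data$cotton) {
    stop("Control cotton '", control, "' not present in the data.", call. = FALSE)
  }
  pooled <- data |>
    dplyr::group_by(.data$strain, .data$year, .data$cotton) |>
    dplyr::summarise(
      survival = sum(.data$n_normal_pupae) / sum(.data$n_larvae),
      .groups = "drop"
    )
  ctrl <- pooled |>
    dplyr::filter(.data$cotton == control) |>
    dplyr::select("strain", "year", survival_control = "survival")
  pooled |>
    dplyr::filter(!.data$cotton %in% c(control, exclude)) |>
    dplyr::left_join(ctrl, by = c("strain", "year")) |>
    dplyr::mutate(efficacy_pct = efficacy_pct(.data$survival, .data$survival_control)) |>
    dplyr::rename(survival_transgenic = "survival")
}

#' Index of multiplicative survival (IMS)
#'
#' IMS is the observed survival on a two-trait pyramid divided by the survival
#' expected under independent action of the two traits, namely the product of
#' the survivals on each single-trait cotton. Survivals are first adjusted by
#' dividing by the survival on the non-transgenic control of the same strain,
#' year and replicate, so the index isolates the transgene effects. An IMS of
#' 1 indicates independent action; the one-sample t-test asks whether the mean
#' replicate IMS differs from 1.
#'
#' Replicates are paired by `(strain, year, replicate)` across the four cotton
#' types. Pass several pyramids (e.g. `pyramid = c("Bt+JHA", "Bt+JHB")` with
#' matching `trait_b`) to pool their replicate IMS values into a single test,
#' as in an analysis that pools both pyramids (df = number of pooled replicate
#' values minus 1).
#'
#' @param data Bioassay tibble.
#' @param pyramid Cotton label(s) of the pyramid(s).
#' @param trait_a Cotton label of the first single-trait plant shared by all
#'   pyramids (e.g. `"Bt"`).
#' @param trait_b Cotton label(s) of the second single-trait plant, one per
#'   pyramid (recycled if length 1).
#' @param control Non-transgenic control cotton label.
#' @param strain Strain to analyse (default the only strain present; required
#'   if several).
#' @return An `ims_result` with `per_replicate` (tibble of replicate-level
#'   adjusted survivals and IMS), `ims` (mean), `se`, `t_stat`, `df`,
#'   `p_value`. Replicates with an expected survival of zero are excluded
#'   with a warning. `tidy()` returns the per-replicate table; `glance()` the
#'   one-row test summary.
#' @export
ims <- function(data, pyramid, trait_a, trait_b, control = "W0",
                strain = NULL) {
  data <- summarize_bioassay(data)
  if (is.null(strain)) {
    strain <- unique(data$strain)
    if (length(strain) > 1) {
      stop("Several strains present; pass `strain` explicitly.", call. = FALSE)
    }
  }
  trait_b <- rep_len(trait_b, length(pyramid))
  data <- dplyr::filter(data, .data$strain == !!strain)
  surv_of <- function(cotton_label) {
    dplyr::filter(data, .data$cotton == cotton_label) |>
      dplyr::select("year", "replicate", survival = "survival")
  }
  per_rep <- purrr::map2_dfr(pyramid, trait_b, function(pyr, tb) {
    tab <- surv_of(pyr) |>
      dplyr::rename(s_pyramid = "survival") |>
      dplyr::inner_join(dplyr::rename(surv_of(trait_a), s_a = "survival"),
                        by = c("year", "replicate")) |>
      dplyr::inner_join(dplyr::rename(surv_of(tb), s_b = "survival"),
                        by = c("year", "replicate")) |>
      dplyr::inner_join(dplyr::rename(surv_of(control), s_control = "survival"),
                        by = c("year", "replicate"))
    dplyr::mutate(tab, pyramid = pyr, .before = 1)
  })
  if (nrow(per_rep) == 0) {
    stop("No replicate-matched records found for the requested cotton types.",
         call. = FALSE)
  }
  per_rep <- per_rep |>
    dplyr::mutate(
      adj_pyramid = .data$s_pyramid / .data$s_control,
      adj_a = .data$s_a / .data$s_control,
      adj_b = .data$s_b / .data$s_control,
      expected = .data$adj_a * .data$adj_b,
      ims = ifelse(.data$expected > 0, .data$adj_pyramid / .data$expected, NA_real_)
    )
  n_dropped <- sum(is.na(per_rep$ims))
  if (n_dropped > 0) {
    warning(n_dropped, " replicate(s) excluded: expected pyramid survival is zero.",
            call. = FALSE)
  }
  vals <- per_rep$ims[!is.na(per_rep$ims)]
  if (length(vals) >= 2 && stats::sd(vals) > 0) {
    tt <- stats::t.test(vals, mu = 1)
    t_stat <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- tt$p.value
  } else {
    t_stat <- NA_real_; df <- NA_real_
    p <- if (length(vals) >= 2 && all(vals == 1)) 1 else NA_real_
  }
  structure(
    list(per_replicate = per_rep,
         ims = mean(vals), se = stats::sd(vals) / sqrt(length(vals)),
         n = length(vals), t_stat = t_stat, df = df, p_value = p,
         strain = strain),
    class = "ims_result"
  )
}

#' @export
print.ims_result <- function(x, ...) {
  cat(sprintf("<ims_result> strain %s: mean IMS = %.3g (SE %.3g, n = %d)\n",
              x$strain, x$ims, x$se, x$n))
  if (!is.na(x$t_stat)) {
    cat(sprintf("  one-sample t vs 1: t = %.3g, df = %g, P = %.3g\n",
                x$t_stat, x$df, x$p_value))
  }
  invisible(x)
}

#' qPCR relative expression (2^-dCt and 2^-ddCt)
#'
#' In dCt mode, relative expression is `2^-(ct_target - ct_reference)`, i.e.
#' transcription relative to the reference gene (e.g. actin). In ddCt mode the
#' target/reference difference is additionally normalized by the calibrator
#' sample's difference:
#' `2^-((ct_target - ct_reference) - (ct_target_calibrator - ct_reference_calibrator))`.
#'
#' @param ct_target,ct_reference Cycle-threshold values (vectorized).
#' @param ct_target_calibrator,ct_reference_calibrator Calibrator Ct values;
#'   both required for ddCt mode, both omitted for dCt mode.
#' @return Fold value(s).
#' @examples
#' relative_expression(21, 20)        # 2^-1 = 0.5
#' relative_expression(21, 20, 23, 20)  # ddCt = -2 -> 4
#' @export
relative_expression <- function(ct_target, ct_reference,
                                ct_target_calibrator = NULL,
                                ct_reference_calibrator = NULL) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop("Ct values must be finite.", call. = FALSE)
  }
  d_ct <- ct_target - ct_reference
  has_cal <- !is.null(ct_target_calibrator) || !is.null(ct_reference_calibrator)
  if (has_cal) {
    if (is.null(ct_target_calibrator) || is.null(ct_reference_calibrator)) {
      stop("ddCt mode needs both calibrator Ct values.", call. = FALSE)
    }
    d_ct <- d_ct - (ct_target_calibrator - ct_reference_calibrator)
  }
  2^(-d_ct)
}
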