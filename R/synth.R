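# Synthetic data generation.
#
# Emulates the study design of the cotton leaf bioassays (2 strains x 7
# cotton types x 2 years x 3 replicates x 50 larvae), paired qPCR Ct tables,
# and transcript panels with planted exact k-mer matches, so every analysis
# stage is testable without external data. A single integer seed governs all
# streams: each generator derives its own sub-seed as
# (seed * 31 + stream offset) mod 2^31 - 1, so modules are independently yet
# reproducibly seeded.

sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offset <- c(bioassay = 1, dev_times = 2, qpcr = 3, panel = 4)[[stream]]
  as.integer((abs(seed) * 31 + offset) %% (2^31 - 1))
}

#' Bioassay design for the synthetic generator
#'
#' Defaults reproduce the study design: susceptible (SCD) and Bt-resistant
#' (SCD-r1) strains on seven cotton types — non-transgenic parent (W0),
#' transgenic control (GFP), Bt, two RNAi cottons (JHA, JHB) and two pyramids
#' (Bt+JHA, Bt+JHB) — in two years, three replicates of 50 larvae each.
#'
#' The default survival map encodes the bioassay outcome structure: both
#' strains survive well on the controls; Bt cotton kills most susceptible
#' larvae but barely affects the resistant strain; the RNAi cottons reduce
#' survival of both strains similarly (no cross-resistance); pyramids combine
#' the two trait effects multiplicatively (independent action). Development
#' times are approximately normal within the 14-30 day recording window, with
#' longer development on the transgenic cottons and a developmental fitness
#' cost in the resistant strain on control plants.
#'
#' @param strains,cottons,years Character vectors of design levels.
#' @param replicates Replicates per cell (default 3).
#' @param larvae_per_replicate Larvae per replicate (default 50).
#' @param survival_prob Data frame with columns `strain`, `cotton`,
#'   `survival_prob` covering every strain x cotton cell (shared across
#'   years), or `NULL` for the defaults.
#' @param dev_time Data frame with columns `strain`, `cotton`,
#'   `dev_time_mean`, `dev_time_sd`, or `NULL` for defaults.
#' @param seed Integer seed governing all randomness in [generate_bioassay()].
#' @return A `bioassay_design` list.
#' @export
bioassay_design <- function(strains = c("SCD", "SCD-r1"),
                            cottons = c("W0", "GFP", "Bt", "JHA", "JHB",
                                        "Bt+JHA", "Bt+JHB"),
                            years = c("2015", "2016"),
                            replicates = 3, larvae_per_replicate = 50,
                            survival_prob = NULL, dev_time = NULL,
                            seed = 1) {
  if (is.null(survival_prob)) {
    survival_prob <- default_survival_map()
  }
  survival_prob <- dplyr::filter(survival_prob, .data$strain %in% strains,
                                 .data$cotton %in% cottons)
  full <- tidyr::expand_grid(strain = strains, cotton = cottons)
  if (nrow(dplyr::anti_join(full, survival_prob, by = c("strain", "cotton"))) > 0) {
    stop("`survival_prob` must cover every strain x cotton cell.", call. = FALSE)
  }
  stopifnot(all(survival_prob$survival_prob >= 0),
            all(survival_prob$survival_prob <= 1))
  if (is.null(dev_time)) dev_time <- default_dev_time_map(full)
  stopifnot(all(dev_time$dev_time_sd > 0))
  structure(
    list(strains = strains, cottons = cottons, years = years,
         replicates = as.integer(replicates),
         larvae_per_replicate = as.integer(larvae_per_replicate),
         survival_prob = survival_prob, dev_time = dev_time,
         seed = seed),
    class = "bioassay_design"
  )
}

# Survival proportions per strain x cotton, anchored on the printed bioassay
# outcomes: SCD control survival 0.84; Bt efficacy ~79% against SCD and ~4%
# against SCD-r1; RNAi efficacies ~63% (JHA) and ~69% (JHB) in both strains;
# pyramid survival = control x product of the two trait effects.
default_survival_map <- function() {
  ctrl <- c("SCD" = 0.84, "SCD-r1" = 0.80)
  bt_effect <- c("SCD" = 0.206, "SCD-r1" = 0.96)     # survival ratio vs control
  jha_effect <- c("SCD" = 0.365, "SCD-r1" = 0.415)
  jhb_effect <- c("SCD" = 0.325, "SCD-r1" = 0.33)
  purrr::map_dfr(c("SCD", "SCD-r1"), function(st) {
    tibble::tibble(
      strain = st,
      cotton = c("W0", "GFP", "Bt", "JHA", "JHB", "Bt+JHA", "Bt+JHB"),
      survival_prob = ctrl[[st]] * c(1, 1, bt_effect[[st]],
                                     jha_effect[[st]], jhb_effect[[st]],
                                     bt_effect[[st]] * jha_effect[[st]],
                                     bt_effect[[st]] * jhb_effect[[st]])
    )
  })
}

default_dev_time_map <- function(cells) {
  base <- c("W0" = 18, "GFP" = 18, "Bt" = 21, "JHA" = 21.8, "JHB" = 21.8,
            "Bt+JHA" = 23.2, "Bt+JHB" = 23.1)
  dplyr::mutate(
    cells,
    dev_time_mean = unname(base[.data$cotton]) +
      ifelse(.data$strain == "SCD-r1" & .data$cotton %in% c("W0", "GFP"), 2.8, 0),
    dev_time_sd = 1.5
  )
}

#' Generate a synthetic bioassay dataset
#'
#' Draws `n_normal_pupae ~ Binomial(n_larvae, survival_prob)` for every
#' strain x cotton x year x replicate cell, and per-survivor development
#' times from a normal distribution truncated to the 14-30 day recording
#' window. Deterministic under the design's seed.
#'
#' @param design A [bioassay_design()].
#' @return Bioassay tibble (one replicate per row) with a `dev_times_days`
#'   list-column, ready for [summarize_bioassay()] and friends.
#' @examples
#' d <- generate_bioassay(bioassay_design(seed = 7))
#' nrow(d)  # 2 strains x 7 cottons x 2 years x 3 replicates = 84
#' @export
generate_bioassay <- function(design) {
  stopifnot(inherits(design, "bioassay_design"))
  grid <- tidyr::expand_grid(
    strain = design$strains, cotton = design$cottons, year = design$years,
    replicate = seq_len(design$replicates)
  ) |>
    dplyr::left_join(design$survival_prob, by = c("strain", "cotton")) |>
    dplyr::left_join(design$dev_time, by = c("strain", "cotton"))
  out <- withr::with_seed(sub_seed(design$seed, "bioassay"), {
    grid$n_larvae <- design$larvae_per_replicate
    grid$n_normal_pupae <- stats::rbinom(nrow(grid), grid$n_larvae,
                                         grid$survival_prob)
    grid$dev_times_days <- purrr::pmap(
      list(grid$n_normal_pupae, grid$dev_time_mean, grid$dev_time_sd),
      function(n, mu, sd) round(rtruncnorm(n, mu, sd, 14, 30), 1)
    )
    grid
  })
  dplyr::select(out, "strain", "cotton", "year", "replicate", "n_larvae",
                "n_normal_pupae", "dev_times_days")
}

# Truncated-normal draws by inverse-CDF, exact on the truncation window.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (n == 0) return(numeric(0))
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

#' Generate a synthetic qPCR Ct table
#'
#' Emits paired target/reference cycle-threshold values per group whose
#' expected `2^-dCt` equals the configured fold change: the target Ct sits
#' `-log2(fold)` cycles above the reference, plus independent measurement
#' noise on each Ct.
#'
#' @param fold_by_group Named numeric vector: expected relative expression
#'   (fold vs. the reference gene) per group, e.g.
#'   `c(W0 = 1, GFP = 1, JHA = 0.3)`.
#' @param n Samples per group.
#' @param noise_sd Ct measurement noise (cycles; 0 gives exact folds).
#' @param ct_reference_mean Mean reference-gene Ct.
#' @param seed Integer seed.
#' @return Tibble: `group`, `sample`, `ct_target`, `ct_reference`. Feed the
#'   Ct columns to [relative_expression()].
#' @export
generate_qpcr <- function(fold_by_group, n = 6, noise_sd = 0.2,
                          ct_reference_mean = 20, seed = 1) {
  stopifnot(is.numeric(fold_by_group), !is.null(names(fold_by_group)),
            all(fold_by_group > 0), n >= 1, noise_sd >= 0)
  withr::with_seed(sub_seed(seed, "qpcr"), {
    purrr::imap_dfr(fold_by_group, function(fold, grp) {
      ct_ref <- ct_reference_mean + stats::rnorm(n, 0, noise_sd)
      tibble::tibble(
        group = grp, sample = seq_len(n),
        ct_target = ct_ref - log2(fold) + stats::rnorm(n, 0, noise_sd),
        ct_reference = ct_ref
      )
    })
  })
}

#' Generate a transcript panel with planted k-mer matches
#'
#' Builds a random dsRNA-fragment sequence and a panel of random transcripts,
#' then copies blocks of the fragment into chosen transcripts so the screen's
#' ground truth is known exactly. Unplanted matches of length >= 21 are
#' vanishingly unlikely at these sizes (expected shared 21-mers between two
#' random 2 kb sequences is ~ 4e-7).
#'
#' @param n_transcripts Panel size.
#' @param transcript_length Length of each transcript (recycled).
#' @param planted Data frame with columns `transcript` (index into the panel)
#'   and `length` (planted block length, >= the screen k you intend to use),
#'   or `NULL` for none. A transcript may receive several blocks.
#' @param fragment_length Length of the dsRNA fragment (default 408 nt, the
#'   size of the JHA trigger fragment).
#' @param seed Integer seed.
#' @return List with `fragment` (one-row tibble), `panel` (tibble of
#'   transcripts) and `manifest` (tibble of planted blocks: `transcript_id`,
#'   `fragment_start`, `transcript_start`, `length`, 0-based half-open).
#' @export
generate_transcript_panel <- function(n_transcripts = 10,
                                      transcript_length = 500,
                                      planted = NULL,
                                      fragment_length = 408, seed = 1) {
  stopifnot(n_transcripts >= 1, fragment_length >= 1)
  lens <- rep_len(transcript_length, n_transcripts)
  if (!is.null(planted)) {
    stopifnot(all(planted$transcript >= 1), all(planted$transcript <= n_transcripts),
              all(planted$length <= fragment_length))
    if (any(planted$length > lens[planted$transcript])) {
      stop("Planted block longer than its target transcript.", call. = FALSE)
    }
  }
  withr::with_seed(sub_seed(seed, "panel"), {
    rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                  collapse = "")
    fragment <- rand_dna(fragment_length)
    panel <- vapply(lens, rand_dna, character(1))
    ids <- sprintf("transcript_%02d", seq_len(n_transcripts))
    manifest <- tibble::tibble(transcript_id = character(),
                               fragment_start = integer(),
                               transcript_start = integer(), length = integer())
    if (!is.null(planted)) {
      for (i in seq_len(nrow(planted))) {
        tr <- planted$transcript[i]
        len <- planted$length[i]
        f0 <- sample.int(fragment_length - len + 1, 1)        # 1-based
        t0 <- sample.int(lens[tr] - len + 1, 1)
        block <- substr(fragment, f0, f0 + len - 1)
        substr(panel[tr], t0, t0 + len - 1) <- block
        # Guard bases: make the planted block non-extendable so the manifest
        # length is exactly the maximal match length.
        mismatch <- function(base) sample(setdiff(c("A", "C", "G", "T"), base), 1)
        if (t0 > 1 && f0 > 1 &&
            substr(panel[tr], t0 - 1, t0 - 1) == substr(fragment, f0 - 1, f0 - 1)) {
          substr(panel[tr], t0 - 1, t0 - 1) <- mismatch(substr(fragment, f0 - 1, f0 - 1))
        }
        tr_end <- t0 + len; f_end <- f0 + len
        if (tr_end <= lens[tr] && f_end <= fragment_length &&
            substr(panel[tr], tr_end, tr_end) == substr(fragment, f_end, f_end)) {
          substr(panel[tr], tr_end, tr_end) <- mismatch(substr(fragment, f_end, f_end))
        }
        manifest <- dplyr::bind_rows(manifest, tibble::tibble(
          transcript_id = ids[tr], fragment_start = f0 - 1L,
          transcript_start = t0 - 1L, length = as.integer(len)
        ))
      }
    }
    list(
      fragment = tibble::tibble(id = "fragment", seq = fragment),
      panel = tibble::tibble(id = ids, seq = panel),
      manifest = manifest
    )
  })
}
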