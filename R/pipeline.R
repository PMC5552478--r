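# End-to-end pipeline: synthetic (or real) bioassay data -> efficacy ->
# scenario parameterization -> durability sweep, with every artifact written
# as plain text and every resolved parameter echoed.

#' Derive a simulation scenario from bioassay efficacy
#'
#' Bridges the bioassay statistics to the simulator: susceptible-homozygote
#' fitness on each transgenic cotton is `w_ss = 1 - efficacy/100`, taking the
#' efficacy of that trait against the susceptible strain from the
#' strain-matched non-transgenic control. When several year-specific
#' efficacies are available the largest is used (the most effective printed
#' value); override per locus via `bt_cotton`/`rnai_cotton` selection or by
#' editing the returned scenario.
#'
#' @param efficacy_tbl Output of [bioassay_efficacy()].
#' @param susceptible_strain Strain whose efficacies parameterize `w_ss`.
#' @param bt_cotton,rnai_cotton Cotton labels providing the Bt and RNAi
#'   single-trait efficacies.
#' @param template Scenario supplying everything except the two `w_ss` values
#'   (default the realistic preset).
#' @return A [scenario()] with the bridged trait-plant fitness values.
#' @examples
#' d <- generate_bioassay(bioassay_design(seed = 1))
#' sc <- bioassay_to_scenario(bioassay_efficacy(d))
#' sc$bt_locus$w_ss
#' @export
bioassay_to_scenario <- function(efficacy_tbl, susceptible_strain = "SCD",
                                 bt_cotton = "Bt", rnai_cotton = "JHA",
                                 template = scenario_presets()$realistic) {
  pick <- function(cotton_label) {
    rows <- dplyr::filter(efficacy_tbl, .data$strain == susceptible_strain,
                          .data$cotton == cotton_label)
    if (nrow(rows) == 0) {
      stop("No efficacy rows for strain ", susceptible_strain, " on ",
           cotton_label, call. = FALSE)
    }
    max(rows$efficacy_pct)
  }
  w_ss_bt <- max(0, 1 - pick(bt_cotton) / 100)
  w_ss_rnai <- max(0, 1 - pick(rnai_cotton) / 100)
  out <- template
  out$bt_locus <- locus_spec(template$bt_locus$name, template$bt_locus$init_r_freq,
                             h = template$bt_locus$h, w_ss = w_ss_bt,
                             w_rr = template$bt_locus$w_rr)
  out$rnai_locus <- locus_spec(template$rnai_locus$name,
                               template$rnai_locus$init_r_freq,
                               h = template$rnai_locus$h, w_ss = w_ss_rnai,
                               w_rr = template$rnai_locus$w_rr)
  out$name <- paste0(template$name, "_from_bioassay")
  out
}

#' Run the full analysis pipeline
#'
#' Executes the stages end to end and writes every artifact under `out_dir`:
#'
#' 1. generate a synthetic bioassay dataset (or ingest `bioassay` if given) —
#'    `bioassay.csv`;
#' 2. per-replicate summaries and transgene efficacies — `summary.tsv`,
#'    `efficacy.tsv`;
#' 3. IMS of both pyramids with the pooled one-sample test — `ims.tsv`;
#' 4. bridge the measured efficacies into the scenario presets and sweep
#'    refuges x strategies — `durability.tsv`, `deltas.tsv`, plus one
#'    trajectory file per scenario at the focal refuge —
#'    `trajectory_<scenario>.tsv`;
#' 5. echo every resolved parameter — `run_config.yaml`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the synthetic data.
#' @param bioassay Optional bioassay tibble to analyse instead of generating
#'   one.
#' @param refuges Refuge fractions for the durability sweep.
#' @param strategies Deployment strategies for the sweep.
#' @param focal_refuge Refuge used for the written trajectories.
#' @return (Invisibly) a list with the in-memory artifacts: `bioassay`,
#'   `efficacy`, `ims`, `scenarios`, `durability`, `deltas`, `paths`.
#' @export
run_pipeline <- function(out_dir, seed = 1, bioassay = NULL,
                         refuges = c(0.05, 0.10, 0.25, 0.50),
                         strategies = c("bt_alone", "sequence", "pyramid"),
                         focal_refuge = 0.50) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)

  synthetic <- is.null(bioassay)
  if (synthetic) {
    bioassay <- generate_bioassay(bioassay_design(seed = seed))
  } else {
    validate_bioassay(bioassay)
  }
  write_bioassay(bioassay, path("bioassay.csv"))

  summary_tbl <- summarize_bioassay(bioassay)
  readr::write_tsv(dplyr::select(summary_tbl, -dplyr::any_of("dev_times_days")),
                   path("summary.tsv"))
  eff <- bioassay_efficacy(bioassay)
  readr::write_tsv(eff, path("efficacy.tsv"))

  ims_res <- ims(bioassay, pyramid = c("Bt+JHA", "Bt+JHB"), trait_a = "Bt",
                 trait_b = c("JHA", "JHB"), strain = "SCD")
  readr::write_tsv(ims_res$per_replicate, path("ims.tsv"))

  bridged <- bioassay_to_scenario(eff)
  presets <- scenario_presets()
  scenarios <- purrr::map(presets, function(p) {
    p$bt_locus <- bridged$bt_locus
    p$rnai_locus <- bridged$rnai_locus
    # pessimistic keeps its own RNAi initial frequency
    p$rnai_locus$init_r_freq <- presets[[p$name]]$rnai_locus$init_r_freq
    p
  })
  durability <- refuge_sweep(scenarios, refuges = refuges,
                             strategies = strategies)
  readr::write_tsv(durability, path("durability.tsv"))
  deltas <- sweep_deltas(durability)
  readr::write_tsv(deltas, path("deltas.tsv"))

  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    sc$refuge_fraction <- focal_refuge
    sim <- time_to_resistance(sc, "pyramid")
    readr::write_tsv(sim$trajectory, path(sprintf("trajectory_%s.tsv", nm)))
  }

  config <- list(
    seed = seed, refuges = refuges, strategies = strategies,
    focal_refuge = focal_refuge,
    bioassay_source = if (synthetic) "synthetic" else "supplied",
    bridged_bt_w_ss = bridged$bt_locus$w_ss,
    bridged_rnai_w_ss = bridged$rnai_locus$w_ss,
    package_version = as.character(utils::packageVersion("btrnai"))
  )
  yaml::write_yaml(config, path("run_config.yaml"))

  invisible(list(bioassay = bioassay, efficacy = eff, ims = ims_res,
                 scenarios = scenarios, durability = durability,
                 deltas = deltas,
                 paths = vapply(c("bioassay.csv", "summary.tsv", "efficacy.tsv",
                                  "ims.tsv", "durability.tsv", "deltas.tsv",
                                  "run_config.yaml"), path, character(1))))
}
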