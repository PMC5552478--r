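#' Specify one resistance locus
#'
#' A locus holds two alleles, `r` (resistance) and `s` (susceptibility).
#' Fitness of the heterozygote on the trait plant is interpolated between the
#' homozygotes by the dominance coefficient `h`:
#' `w_rs = w_ss + h * (w_rr - w_ss)`, so `h = 0` is completely recessive
#' resistance and `h = 1` completely dominant.
#'
#' @param name Label for the locus (e.g. `"bt"`, `"rnai"`).
#' @param init_r_freq Initial frequency of the resistance allele, in `[0, 1]`.
#' @param h Dominance of resistance, in `[0, 1]`.
#' @param w_ss Fitness of the susceptible homozygote on the trait plant,
#'   in `[0, 1]`. Equal to one minus the trait's efficacy expressed as a
#'   proportion.
#' @param w_rr Fitness of the resistant homozygote on the trait plant;
#'   must satisfy `w_ss <= w_rr <= 1`.
#'
#' @return A `locus_spec` object (a named list).
#' @examples
#' locus_spec("bt", init_r_freq = 0.05, h = 0.5, w_ss = 0.206)
#' @export
locus_spec <- function(name, init_r_freq, h = 0.5, w_ss, w_rr = 1) {
  stopifnot(is.character(name), length(name) == 1)
  check_prob(init_r_freq, "init_r_freq")
  check_prob(h, "h")
  check_prob(w_ss, "w_ss")
  check_prob(w_rr, "w_rr")
  if (w_ss > w_rr) {
    stop("`w_ss` must not exceed `w_rr`: resistance cannot be harmful on its own trait plant.",
         call. = FALSE)
  }
  structure(
    list(name = name, init_r_freq = init_r_freq, h = h,
         w_ss = w_ss, w_rr = w_rr),
    class = "locus_spec"
  )
}

#' @export
print.locus_spec <- function(x, ...) {
  cat(sprintf("<locus_spec> %s: p0 = %g, h = %g, w_ss = %g, w_rr = %g\n",
              x$name, x$init_r_freq, x$h, x$w_ss, x$w_rr))
  invisible(x)
}

#' Fitness cost of resistance alleles on refuge plants
#'
#' In `additive` mode a genotype carrying `k` resistance alleles (counted
#' across both loci) has fitness `max(0, 1 - k * cost_per_r_allele)` on
#' non-transgenic host plants; in `none` mode refuge fitness is 1 for every
#' genotype.
#'
#' @param cost_per_r_allele Fitness decrement per resistance allele on
#'   non-transgenic plants.
#' @param mode `"none"` or `"additive"`.
#' @return A `cost_model` object.
#' @examples
#' cost_model(0.05)               # doubly resistant homozygote -> 0.80
#' cost_model(0, mode = "none")
#' @export
cost_model <- function(cost_per_r_allele = 0, mode = c("none", "additive")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(cost_per_r_allele), length(cost_per_r_allele) == 1,
            cost_per_r_allele >= 0)
  structure(list(cost_per_r_allele = cost_per_r_allele, mode = mode),
            class = "cost_model")
}

#' Refuge fitness for a genotype with a given resistance-allele count
#'
#' @param cost A [cost_model()].
#' @param n_r_alleles Number of resistance alleles carried (0 to 4 across two
#'   loci).
#' @return Fitness on non-transgenic host plants, in `[0, 1]`.
#' @examples
#' refuge_fitness(cost_model(0.05, "additive"), 4) # 0.80
#' @export
refuge_fitness <- function(cost, n_r_alleles) {
  stopifnot(inherits(cost, "cost_model"), all(n_r_alleles >= 0))
  if (cost$mode == "none") {
    rep(1, length(n_r_alleles))
  } else {
    pmax(0, 1 - n_r_alleles * cost$cost_per_r_allele)
  }
}

#' Assemble a complete simulation scenario
#'
#' A scenario bundles everything the deterministic simulator needs: the two
#' locus specifications, the refuge fitness-cost model, the refuge fraction,
#' the number of pest generations on cotton per year, the population-fitness
#' threshold that defines resistance, and a cap on simulated years.
#'
#' @param bt_locus,rnai_locus [locus_spec()] objects for the Bt-resistance and
#'   RNAi-resistance loci.
#' @param cost A [cost_model()] applied on refuge (non-transgenic) plants.
#' @param refuge_fraction Proportion of the habitat that is non-transgenic,
#'   in `(0, 1)`.
#' @param generations_per_year Pest generations that feed on cotton per year
#'   (3 for *H. armigera* in northern China).
#' @param resistance_threshold Population fitness on the deployed transgenic
#'   cotton at which resistance is declared (default 0.50).
#' @param max_years Stop the simulation after this many years.
#' @param name Optional scenario label.
#' @param hp Optional dominance override for the pyramid. When supplied, the
#'   pyramid's nine-genotype fitness surface is built from a single dominance
#'   coefficient applied between the doubly susceptible and doubly resistant
#'   corner fitnesses, instead of the default per-locus product.
#'
#' @return A `scenario` object.
#' @examples
#' sc <- scenario(
#'   bt_locus   = locus_spec("bt",   0.05,  h = 0.5, w_ss = 0.206),
#'   rnai_locus = locus_spec("rnai", 0.001, h = 0.5, w_ss = 0.34),
#'   refuge_fraction = 0.5
#' )
#' @export
scenario <- function(bt_locus, rnai_locus, cost = cost_model(),
                     refuge_fraction = 0.5, generations_per_year = 3,
                     resistance_threshold = 0.5, max_years = 300,
                     name = "scenario", hp = NULL) {
  stopifnot(inherits(bt_locus, "locus_spec"), inherits(rnai_locus, "locus_spec"),
            inherits(cost, "cost_model"))
  check_prob(refuge_fraction, "refuge_fraction")
  stopifnot(generations_per_year >= 1, generations_per_year == as.integer(generations_per_year),
            resistance_threshold > 0, resistance_threshold <= 1,
            max_years >= 1)
  if (!is.null(hp)) check_prob(hp, "hp")
  structure(
    list(bt_locus = bt_locus, rnai_locus = rnai_locus, cost = cost,
         refuge_fraction = refuge_fraction,
         generations_per_year = as.integer(generations_per_year),
         resistance_threshold = resistance_threshold,
         max_years = max_years, name = name, hp = hp),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s\n", x$name))
  cat(sprintf("  refuge %g%%, %d generations/year, threshold %g, max %g years\n",
              100 * x$refuge_fraction, x$generations_per_year,
              x$resistance_threshold, x$max_years))
  cat(sprintf("  cost: %s (%g per r allele)\n", x$cost$mode, x$cost$cost_per_r_allele))
  print(x$bt_locus); print(x$rnai_locus)
  invisible(x)
}

#' The three published deployment scenarios
#'
#' Returns the realistic, optimistic and pessimistic parameterizations used in
#' the durability analysis:
#' * **realistic** — `h = 0.5` at both loci, no fitness cost, initial
#'   resistance allele frequencies 0.05 (Bt) and 0.001 (RNAi);
#' * **optimistic** — `h = 0.5` for Bt, `h = 0.2` for RNAi, additive cost of
#'   0.05 per resistance allele on refuge plants (doubly resistant homozygote
#'   refuge fitness 0.80);
#' * **pessimistic** — identical to realistic except the initial RNAi
#'   resistance allele frequency is 0.01.
#'
#' Trait-plant fitnesses default to values derived from the bioassay
#' efficacies (`w_ss` on Bt cotton = 1 - 0.794 = 0.206; `w_ss` on RNAi cotton
#' = 1 - 0.66 = 0.34; `w_rr` = 1 at both loci), read from the parameter file
#' bundled at `system.file("extdata", "default_params.yaml", package =
#' "btrnai")`. Pass `params` to drop in a different parameter file (for
#' example, one transcribed from a published supplement).
#'
#' @param refuge_fraction Refuge proportion shared by all three scenarios.
#' @param params Path to a YAML parameter file with keys `bt_w_ss`, `bt_w_rr`,
#'   `rnai_w_ss`, `rnai_w_rr` (others optional; see the bundled file).
#' @param max_years Year cap passed to each [scenario()].
#' @return Named list of three `scenario` objects.
#' @examples
#' presets <- scenario_presets()
#' names(presets)
#' presets$optimistic$rnai_locus$h
#' @export
scenario_presets <- function(refuge_fraction = 0.5, params = NULL,
                             max_years = 300) {
  p <- read_params(params)
  make <- function(name, rnai_init, rnai_h, cost) {
    scenario(
      bt_locus   = locus_spec("bt", p$bt_init_r_freq, h = p$bt_h,
                              w_ss = p$bt_w_ss, w_rr = p$bt_w_rr),
      rnai_locus = locus_spec("rnai", rnai_init, h = rnai_h,
                              w_ss = p$rnai_w_ss, w_rr = p$rnai_w_rr),
      cost = cost, refuge_fraction = refuge_fraction,
      generations_per_year = p$generations_per_year,
      resistance_threshold = p$resistance_threshold,
      max_years = max_years, name = name
    )
  }
  list(
    realistic   = make("realistic", p$rnai_init_r_freq, 0.5, cost_model(0, "none")),
    optimistic  = make("optimistic", p$rnai_init_r_freq, 0.2, cost_model(0.05, "additive")),
    pessimistic = make("pessimistic", 0.01, 0.5, cost_model(0, "none"))
  )
}

# Resolve the default parameter file; fall back to built-in values when the
# package is not installed (e.g. during load_all()).
read_params <- function(path = NULL) {
  defaults <- list(
    bt_init_r_freq = 0.05, bt_h = 0.5, bt_w_ss = 0.206, bt_w_rr = 1,
    rnai_init_r_freq = 0.001, rnai_w_ss = 0.34, rnai_w_rr = 1,
    generations_per_year = 3L, resistance_threshold = 0.5
  )
  if (is.null(path)) {
    path <- system.file("extdata", "default_params.yaml", package = "btrnai")
    if (identical(path, "")) return(defaults)
  }
  if (!file.exists(path)) stop("Parameter file not found: ", path, call. = FALSE)
  p <- yaml::read_yaml(path)
  utils::modifyList(defaults, p[names(p) %in% names(defaults)])
}

#' Write / read a scenario as a flat YAML file
#'
#' Scenario files are flat key-value YAML whose keys match the field names of
#' [locus_spec()], [cost_model()] and [scenario()], prefixed `bt_` and `rnai_`
#' for the two loci.
#'
#' @param x A `scenario` object.
#' @param path File path.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns a `scenario`.
#' @export
write_scenario <- function(x, path) {
  stopifnot(inherits(x, "scenario"))
  flat <- list(
    name = x$name,
    bt_init_r_freq = x$bt_locus$init_r_freq, bt_h = x$bt_locus$h,
    bt_w_ss = x$bt_locus$w_ss, bt_w_rr = x$bt_locus$w_rr,
    rnai_init_r_freq = x$rnai_locus$init_r_freq, rnai_h = x$rnai_locus$h,
    rnai_w_ss = x$rnai_locus$w_ss, rnai_w_rr = x$rnai_locus$w_rr,
    cost_mode = x$cost$mode, cost_per_r_allele = x$cost$cost_per_r_allele,
    refuge_fraction = x$refuge_fraction,
    generations_per_year = x$generations_per_year,
    resistance_threshold = x$resistance_threshold,
    max_years = x$max_years
  )
  if (!is.null(x$hp)) flat$hp <- x$hp
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  f <- yaml::read_yaml(path)
  scenario(
    bt_locus   = locus_spec("bt", f$bt_init_r_freq, h = f$bt_h,
                            w_ss = f$bt_w_ss, w_rr = f$bt_w_rr),
    rnai_locus = locus_spec("rnai", f$rnai_init_r_freq, h = f$rnai_h,
                            w_ss = f$rnai_w_ss, w_rr = f$rnai_w_rr),
    cost = cost_model(f$cost_per_r_allele, f$cost_mode),
    refuge_fraction = f$refuge_fraction,
    generations_per_year = f$generations_per_year,
    resistance_threshold = f$resistance_threshold,
    max_years = f$max_years,
    name = f$name %||% "scenario",
    hp = f$hp
  )
}

check_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop("`", what, "` must be a single number in [0, 1].", call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
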