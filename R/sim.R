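# Deterministic two-locus recursion.
#
# The population is censused as a pool of four gamete types
# (r1r2, r1s2, s1r2, s1s2). Random union of gametes gives the nine newborn
# genotypes; selection weighs each genotype by its habitat-averaged fitness;
# the survivors emit the next gamete pool with recombination fraction 0.5
# between the two unlinked autosomal loci. No mutation, migration or drift:
# frequencies evolve deterministically.

GAMETES <- c("r1r2", "r1s2", "s1r2", "s1s2")
.A1 <- c(1, 1, 0, 0)  # r allele at the Bt locus carried by each gamete type
.A2 <- c(1, 0, 1, 0)  # r allele at the RNAi locus
.N1 <- outer(.A1, .A1, "+")  # r1 count of each of the 16 ordered gamete pairs
.N2 <- outer(.A2, .A2, "+")

#' Two-locus state at linkage equilibrium
#'
#' Builds the gamete-frequency state implied by independent allele frequencies
#' at the two loci (linkage disequilibrium D = 0), the natural starting point
#' for two unlinked loci that have not experienced joint selection.
#'
#' @param p1 Resistance allele frequency at the Bt locus.
#' @param p2 Resistance allele frequency at the RNAi locus.
#' @return A `two_locus_state`: gamete frequencies plus a generation counter.
#' @examples
#' hw_state(0.05, 0.001)
#' @export
hw_state <- function(p1, p2) {
  check_prob(p1, "p1")
  check_prob(p2, "p2")
  g <- c(p1 * p2, p1 * (1 - p2), (1 - p1) * p2, (1 - p1) * (1 - p2))
  names(g) <- GAMETES
  structure(list(gamete = g, generation = 0L), class = "two_locus_state")
}

#' @export
print.two_locus_state <- function(x, ...) {
  cat(sprintf("<two_locus_state> generation %d\n", x$generation))
  print(round(x$gamete, 6))
  cat(sprintf("  p1 = %.6g, p2 = %.6g, D = %.3g\n",
              allele_freqs(x)[1], allele_freqs(x)[2], linkage_d(x)))
  invisible(x)
}

#' Allele frequencies and linkage disequilibrium of a state
#'
#' @param state A `two_locus_state`.
#' @return `allele_freqs()` returns `c(p1, p2)`; `linkage_d()` returns
#'   `D = f(r1r2) - p1 * p2`.
#' @export
allele_freqs <- function(state) {
  g <- state$gamete
  c(p1 = unname(g[1] + g[2]), p2 = unname(g[1] + g[3]))
}

#' @rdname allele_freqs
#' @export
linkage_d <- function(state) {
  p <- allele_freqs(state)
  unname(state$gamete[1] - p[1] * p[2])
}

#' Genotype fitness at a single locus
#'
#' Heterozygote fitness is the dominance interpolation
#' `w_rs = w_ss + h * (w_rr - w_ss)`.
#'
#' @param locus A [locus_spec()].
#' @param genotype `"ss"`, `"rs"` or `"rr"` (vectorized).
#' @return Fitness value(s) on the locus's trait plant.
#' @examples
#' bt <- locus_spec("bt", 0.05, h = 0.5, w_ss = 0.21)
#' single_locus_fitness(bt, c("ss", "rs", "rr"))
#' @export
single_locus_fitness <- function(locus, genotype) {
  stopifnot(inherits(locus, "locus_spec"))
  w <- c(ss = locus$w_ss,
         rs = locus$w_ss + locus$h * (locus$w_rr - locus$w_ss),
         rr = locus$w_rr)
  if (!all(genotype %in% names(w))) {
    stop('`genotype` must be one of "ss", "rs", "rr".', call. = FALSE)
  }
  unname(w[genotype])
}

#' Nine-genotype fitness model for a deployment
#'
#' Assembles the 3 x 3 (Bt genotype x RNAi genotype) fitness tables on the
#' deployed transgenic cotton and on refuge plants.
#'
#' On Bt cotton only the Bt locus matters; on RNAi cotton only the RNAi locus;
#' on the pyramid the default fitness is the per-genotype product of the two
#' single-trait fitnesses (independent action of the Bt toxin and the dsRNA,
#' as supported by the index of multiplicative survival). When the scenario
#' carries an `hp` override, pyramid fitness is instead built from a single
#' dominance coefficient: genotypes with at least one resistance allele at
#' both loci sit at `w_ss_pyr + hp * (w_rr_pyr - w_ss_pyr)` (the double
#' homozygote at `w_rr_pyr`), genotypes susceptible at either locus at
#' `w_ss_pyr`. Refuge fitness depends only on the number of resistance
#' alleles, through the cost model.
#'
#' @param scenario A [scenario()].
#' @param deployed `"bt"`, `"rnai"` or `"pyramid"`.
#' @return A `fitness_model`: list of two 3 x 3 matrices `w_transgenic` and
#'   `w_refuge`, rows = Bt genotype (ss, rs, rr), cols = RNAi genotype.
#' @examples
#' sc <- scenario_presets()$realistic
#' build_fitness_model(sc, "pyramid")$w_transgenic
#' @export
build_fitness_model <- function(scenario, deployed = c("bt", "rnai", "pyramid")) {
  stopifnot(inherits(scenario, "scenario"))
  deployed <- match.arg(deployed)
  gt <- c("ss", "rs", "rr")
  w_bt <- single_locus_fitness(scenario$bt_locus, gt)
  w_rn <- single_locus_fitness(scenario$rnai_locus, gt)
  w_trans <- switch(
    deployed,
    bt      = matrix(w_bt, 3, 3),
    rnai    = matrix(w_rn, 3, 3, byrow = TRUE),
    pyramid = {
      if (is.null(scenario$hp)) {
        outer(w_bt, w_rn)
      } else {
        lo <- w_bt[1] * w_rn[1]
        hi <- w_bt[3] * w_rn[3]
        m <- matrix(lo, 3, 3)
        m[2:3, 2:3] <- lo + scenario$hp * (hi - lo)
        m[3, 3] <- hi
        m
      }
    }
  )
  n_r <- outer(0:2, 0:2, "+")
  w_ref <- matrix(refuge_fitness(scenario$cost, as.vector(n_r)), 3, 3)
  dimnames(w_trans) <- dimnames(w_ref) <- list(bt = gt, rnai = gt)
  structure(list(w_transgenic = w_trans, w_refuge = w_ref,
                 deployed = deployed),
            class = "fitness_model")
}

#' Newborn genotype frequencies implied by a gamete pool
#'
#' @param state A `two_locus_state`.
#' @return 3 x 3 matrix of genotype frequencies under random union of
#'   gametes; rows = Bt genotype (ss, rs, rr), cols = RNAi genotype.
#' @export
genotype_freqs <- function(state) {
  P <- outer(state$gamete, state$gamete)
  G <- matrix(0, 3, 3, dimnames = list(bt = c("ss", "rs", "rr"),
                                       rnai = c("ss", "rs", "rr")))
  for (i in 0:2) for (j in 0:2) {
    G[i + 1, j + 1] <- sum(P[.N1 == i & .N2 == j])
  }
  G
}

#' Advance the population one generation
#'
#' One generation is: random union of the gamete pool into the nine newborn
#' genotypes; selection, with each genotype's realized fitness the
#' habitat-weighted average
#' `refuge_fraction * w_refuge + (1 - refuge_fraction) * w_transgenic`
#' (larvae are distributed over habitats in proportion to area); and
#' production of the next gamete pool by the surviving, randomly mating
#' adults, with recombination fraction 0.5 between the unlinked loci.
#'
#' @param state A `two_locus_state`.
#' @param fitness A `fitness_model` from [build_fitness_model()].
#' @param refuge_fraction Proportion of the habitat that is non-transgenic.
#' @return The next `two_locus_state` (generation counter incremented).
#' @export
step_generation <- function(state, fitness, refuge_fraction) {
  stopifnot(inherits(state, "two_locus_state"), inherits(fitness, "fitness_model"))
  check_prob(refuge_fraction, "refuge_fraction")
  x <- state$gamete
  P <- outer(x, x)                                   # 16 ordered gamete pairs
  idx <- cbind(as.vector(.N1) + 1L, as.vector(.N2) + 1L)
  w <- refuge_fraction * fitness$w_refuge[idx] +
    (1 - refuge_fraction) * fitness$w_transgenic[idx]
  Q <- as.vector(P) * w
  W <- sum(Q)
  if (W <= 0) {
    stop("Population extinct: mean fitness is zero under this fitness model.",
         call. = FALSE)
  }
  Q <- Q / W
  # Each surviving parent transmits r at a locus with probability
  # (r-allele count at that locus)/2, independently across unlinked loci.
  h1 <- as.vector(.N1) / 2
  h2 <- as.vector(.N2) / 2
  g <- c(sum(Q * h1 * h2), sum(Q * h1 * (1 - h2)),
         sum(Q * (1 - h1) * h2), sum(Q * (1 - h1) * (1 - h2)))
  g <- g / sum(g)
  names(g) <- GAMETES
  structure(list(gamete = g, generation = state$generation + 1L),
            class = "two_locus_state")
}

#' Population fitness on the deployed transgenic cotton
#'
#' The sum of the nine genotype fitnesses on the transgenic cotton weighted by
#' the proportion of each genotype among newborns of the current generation
#' (census before that generation's selection).
#'
#' @inheritParams step_generation
#' @return A fitness value in `[0, 1]`.
#' @export
population_fitness <- function(state, fitness) {
  sum(genotype_freqs(state) * fitness$w_transgenic)
}

#' Simulate resistance evolution under one deployment
#'
#' Runs the deterministic recursion until the population's fitness on the
#' deployed transgenic cotton reaches the scenario's resistance threshold
#' (default 0.50), evaluated on each generation's newborns, or until
#' `max_years` is exhausted. Years are fractional: a population crossing the
#' threshold at generation g has `years_to_resistance = g /
#' generations_per_year`, so differences of one generation appear as 1/3 year
#' under the default three cotton generations per year.
#'
#' For `"bt_alone"` and `"rnai_alone"` the unused locus is held fixed (no
#' resistance variation at it), so those runs are effectively single-locus.
#'
#' @param scenario A [scenario()].
#' @param strategy `"bt_alone"`, `"rnai_alone"` or `"pyramid"`. For a
#'   sequential release of the two traits use [sequence_time()].
#' @return A `resistance_sim` object with elements `trajectory` (tibble:
#'   generation, year, p1, p2, D, pop_fitness), `years_to_resistance`
#'   (fractional years, `NA` if the threshold was never reached), `reached`,
#'   `strategy` and `scenario`. [tidy()][generics::tidy] extracts the
#'   trajectory, [glance()][generics::glance] the one-row summary, and
#'   `autoplot()` draws the trajectory.
#' @examples
#' sc <- scenario_presets()$realistic
#' sim <- time_to_resistance(sc, "bt_alone")
#' glance(sim)
#' @export
time_to_resistance <- function(scenario,
                               strategy = c("bt_alone", "rnai_alone", "pyramid")) {
  stopifnot(inherits(scenario, "scenario"))
  strategy <- match.arg(strategy)
  deployed <- switch(strategy, bt_alone = "bt", rnai_alone = "rnai",
                     pyramid = "pyramid")
  p1 <- if (strategy == "rnai_alone") 0 else scenario$bt_locus$init_r_freq
  p2 <- if (strategy == "bt_alone") 0 else scenario$rnai_locus$init_r_freq
  fit <- build_fitness_model(scenario, deployed)
  gpy <- scenario$generations_per_year
  max_gen <- scenario$max_years * gpy

  state <- hw_state(p1, p2)
  n <- max_gen + 1L
  traj <- matrix(NA_real_, nrow = n, ncol = 4,
                 dimnames = list(NULL, c("p1", "p2", "D", "pop_fitness")))
  p <- allele_freqs(state)
  traj[1, ] <- c(p[1], p[2], linkage_d(state), population_fitness(state, fit))
  years <- NA_real_
  g_final <- 0L
  for (g in seq_len(max_gen)) {
    state <- step_generation(state, fit, scenario$refuge_fraction)
    p <- allele_freqs(state)
    pf <- population_fitness(state, fit)
    traj[g + 1L, ] <- c(p[1], p[2], linkage_d(state), pf)
    g_final <- g
    if (pf >= scenario$resistance_threshold) {
      years <- g / gpy
      break
    }
  }
  trajectory <- tibble::tibble(
    generation = 0:g_final,
    year = (0:g_final) / gpy,
    p1 = traj[1:(g_final + 1L), "p1"],
    p2 = traj[1:(g_final + 1L), "p2"],
    D = traj[1:(g_final + 1L), "D"],
    pop_fitness = traj[1:(g_final + 1L), "pop_fitness"]
  )
  structure(
    list(trajectory = trajectory, years_to_resistance = years,
         reached = !is.na(years), strategy = strategy, scenario = scenario),
    class = "resistance_sim"
  )
}

#' @export
print.resistance_sim <- function(x, ...) {
  cat(sprintf("<resistance_sim> %s, %s, refuge %g%%\n",
              x$scenario$name, x$strategy, 100 * x$scenario$refuge_fraction))
  if (x$reached) {
    cat(sprintf("  resistance after %.2f years (generation %d)\n",
                x$years_to_resistance, max(x$trajectory$generation)))
  } else {
    cat(sprintf("  resistance not reached within %g years\n", x$scenario$max_years))
  }
  invisible(x)
}

#' Durability of a sequential release
#'
#' The time to resistance for a sequence of Bt cotton followed by RNAi cotton
#' is the sum of the time for resistance to Bt cotton alone and the time for
#' resistance to RNAi cotton alone, each run from its own initial resistance
#' allele frequency.
#'
#' @param scenario A [scenario()].
#' @return Fractional years (numeric scalar); `NA` if either component never
#'   reaches the threshold.
#' @export
sequence_time <- function(scenario) {
  t_bt <- time_to_resistance(scenario, "bt_alone")$years_to_resistance
  t_rn <- time_to_resistance(scenario, "rnai_alone")$years_to_resistance
  if (is.na(t_bt) || is.na(t_rn)) NA_real_ else t_bt + t_rn
}

#' Durability table over refuges, strategies and scenarios
#'
#' Runs every combination of scenario, refuge fraction and deployment
#' strategy and tabulates the years to resistance, together with each
#' strategy's delta against Bt cotton alone at the same refuge.
#'
#' @param scenarios A [scenario()] or a (optionally named) list of scenarios;
#'   each is re-run at every requested refuge fraction.
#' @param refuges Numeric vector of refuge proportions.
#' @param strategies Subset of `c("bt_alone", "rnai_alone", "sequence",
#'   "pyramid")`.
#' @return A tibble with columns `scenario`, `strategy`, `refuge`,
#'   `years_to_resistance`, `reached`, `delta_vs_bt_alone` (`NA` where
#'   `bt_alone` was not run or not reached).
#' @examples
#' sc <- scenario_presets()$realistic
#' refuge_sweep(sc, refuges = c(0.05, 0.5),
#'              strategies = c("bt_alone", "pyramid"))
#' @export
refuge_sweep <- function(scenarios, refuges = c(0.05, 0.10, 0.25, 0.50),
                         strategies = c("bt_alone", "sequence", "pyramid")) {
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  stopifnot(length(refuges) > 0, length(strategies) > 0,
            all(strategies %in% c("bt_alone", "rnai_alone", "sequence", "pyramid")))
  if (is.null(names(scenarios))) {
    names(scenarios) <- vapply(scenarios, function(s) s$name, character(1))
  }
  grid <- tidyr::expand_grid(
    scenario = names(scenarios),
    refuge = refuges,
    strategy = strategies
  )
  res <- purrr::pmap_dfr(grid, function(scenario, refuge, strategy) {
    sc <- scenarios[[scenario]]
    sc$refuge_fraction <- refuge
    yrs <- if (strategy == "sequence") {
      sequence_time(sc)
    } else {
      time_to_resistance(sc, strategy)$years_to_resistance
    }
    tibble::tibble(scenario = scenario, strategy = strategy, refuge = refuge,
                   years_to_resistance = yrs, reached = !is.na(yrs))
  })
  dplyr::group_by(res, .data$scenario, .data$refuge) |>
    dplyr::mutate(
      delta_vs_bt_alone = .data$years_to_resistance -
        .data$years_to_resistance[match("bt_alone", .data$strategy)]
    ) |>
    dplyr::ungroup()
}

#' Strategy deltas from a durability table
#'
#' Pivots a [refuge_sweep()] result to one row per scenario x refuge with the
#' two headline contrasts: years added by the sequence over Bt alone, and
#' years added by the pyramid over the sequence.
#'
#' @param sweep_tbl Output of [refuge_sweep()] run with at least the
#'   `bt_alone`, `sequence` and `pyramid` strategies.
#' @return Tibble with columns `scenario`, `refuge`, `bt_alone`, `sequence`,
#'   `pyramid`, `sequence_minus_bt_alone`, `pyramid_minus_sequence`,
#'   `pyramid_minus_bt_alone`.
#' @export
sweep_deltas <- function(sweep_tbl) {
  wide <- sweep_tbl |>
    dplyr::select("scenario", "strategy", "refuge", "years_to_resistance") |>
    tidyr::pivot_wider(names_from = "strategy",
                       values_from = "years_to_resistance")
  for (col in c("bt_alone", "sequence", "pyramid")) {
    if (!col %in% names(wide)) {
      stop("`sweep_tbl` must contain the ", col, " strategy.", call. = FALSE)
    }
  }
  dplyr::mutate(
    wide,
    sequence_minus_bt_alone = .data$sequence - .data$bt_alone,
    pyramid_minus_sequence = .data$pyramid - .data$sequence,
    pyramid_minus_bt_alone = .data$pyramid - .data$bt_alone
  )
}

#' Expected double-homozygote fraction among selfed F2 offspring
#'
#' Selfing a plant heterozygous at `n_loci` unlinked loci yields homozygotes
#' for the chosen allele at every locus in a fraction `(1/4)^n_loci` of the F2
#' generation: 1/16 for the two-trait pyramid.
#'
#' @param n_loci Number of unlinked heterozygous loci (>= 1).
#' @return Expected proportion.
#' @examples
#' expected_double_homozygote_fraction(2)  # 1/16
#' @export
expected_double_homozygote_fraction <- function(n_loci) {
  if (!is.numeric(n_loci) || length(n_loci) != 1 || n_loci < 1 ||
      n_loci != as.integer(n_loci)) {
    stop("`n_loci` must be a positive integer.", call. = FALSE)
  }
  (1 / 4)^n_loci
}
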