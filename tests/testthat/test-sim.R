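# Deterministic two-locus simulator.

bt_default <- locus_spec("bt", 0.05, h = 0.5, w_ss = 0.206)
rnai_default <- locus_spec("rnai", 0.001, h = 0.5, w_ss = 0.34)

base_scenario <- function(...) {
  args <- utils::modifyList(
    list(bt_locus = bt_default, rnai_locus = rnai_default,
         refuge_fraction = 0.5, max_years = 300),
    list(...)
  )
  do.call(scenario, args)
}

test_that("linkage-equilibrium initialization gives product gamete frequencies", {
  expect_equal(unname(hw_state(0, 0)$gamete), c(0, 0, 0, 1))
  expect_equal(unname(hw_state(1, 1)$gamete), c(1, 0, 0, 0))
  s <- hw_state(0.05, 0.001)
  expect_equal(unname(s$gamete),
               c(5e-5, 0.04995, 9.5e-4, 0.94905))
  expect_equal(s$generation, 0L)
  expect_equal(unname(allele_freqs(s)), c(0.05, 0.001))
  expect_equal(linkage_d(s), 0)
  expect_error(hw_state(-0.1, 0.5), "p1")
  expect_error(hw_state(0.5, 1.2), "p2")
})

test_that("heterozygote fitness is the dominance interpolation", {
  l <- locus_spec("x", 0.1, h = 0.5, w_ss = 0.21, w_rr = 1)
  expect_equal(single_locus_fitness(l, "rs"), 0.605)
  expect_equal(single_locus_fitness(locus_spec("x", 0.1, h = 0, w_ss = 0.21), "rs"),
               0.21)
  expect_equal(single_locus_fitness(locus_spec("x", 0.1, h = 0.2, w_ss = 0.34), "rs"),
               0.472)
  expect_equal(single_locus_fitness(l, c("ss", "rs", "rr")), c(0.21, 0.605, 1))
  expect_error(single_locus_fitness(l, "sr"), "genotype")
  expect_error(locus_spec("x", 0.1, w_ss = 0.9, w_rr = 0.5), "w_rr")
})

test_that("refuge fitness follows the additive cost model", {
  add <- cost_model(0.05, "additive")
  expect_equal(refuge_fitness(add, 0:4), c(1, 0.95, 0.90, 0.85, 0.80))
  expect_equal(refuge_fitness(cost_model(0.4, "additive"), 4), 0)  # floored
  expect_equal(refuge_fitness(cost_model(0.3, "none"), 0:4), rep(1, 5))
})

test_that("fitness model assembly: refuge cost, pyramid product, deployments", {
  sc <- base_scenario(cost = cost_model(0.05, "additive"))
  fm <- build_fitness_model(sc, "pyramid")
  expect_equal(fm$w_refuge["rr", "rr"], 0.80)
  expect_equal(fm$w_refuge["ss", "ss"], 1)
  # multiplicative assembly on the pyramid
  expect_equal(fm$w_transgenic["ss", "ss"],
               0.206 * 0.34)
  expect_equal(fm$w_transgenic["rr", "ss"], 1 * 0.34)
  sc2 <- base_scenario(bt_locus = locus_spec("bt", 0.05, h = 0.5, w_ss = 0.21),
                       rnai_locus = locus_spec("rnai", 0.001, h = 0.5, w_ss = 0.34))
  expect_equal(build_fitness_model(sc2, "pyramid")$w_transgenic["ss", "ss"],
               0.0714)
  # cost mode none: all refuge fitnesses 1
  expect_true(all(build_fitness_model(base_scenario(), "bt")$w_refuge == 1))
  # single-trait deployments ignore the other locus
  fb <- build_fitness_model(sc, "bt")$w_transgenic
  expect_true(all(fb[, 1] == fb[, 2]) && all(fb[, 2] == fb[, 3]))
  fr <- build_fitness_model(sc, "rnai")$w_transgenic
  expect_true(all(fr[1, ] == fr[2, ]) && all(fr[2, ] == fr[3, ]))
  expect_error(build_fitness_model(sc, "stacked"))
})

test_that("one generation of selection matches a single-locus brute force", {
  # p1 = 0.05, 50% refuge, w = (0.21, 0.605, 1.0), no cost, single locus
  sc <- base_scenario(bt_locus = locus_spec("bt", 0.05, h = 0.5, w_ss = 0.21))
  fm <- build_fitness_model(sc, "bt")
  st <- step_generation(hw_state(0.05, 0), fm, 0.5)
  expected_p1 <- single_locus_next_p(0.05, c(0.21, 0.605, 1), 0.5)
  expect_equal(unname(allele_freqs(st)["p1"]), expected_p1, tolerance = 1e-12)
  expect_equal(st$generation, 1L)
})

test_that("neutral fitness leaves the state unchanged for many generations", {
  sc <- base_scenario(bt_locus = locus_spec("bt", 0.3, h = 0.5, w_ss = 1),
                      rnai_locus = locus_spec("rnai", 0.2, h = 0.5, w_ss = 1))
  fm <- build_fitness_model(sc, "pyramid")
  st <- hw_state(0.3, 0.2)
  g0 <- st$gamete
  for (i in 1:1000) st <- step_generation(st, fm, 0.5)
  expect_equal(st$gamete, g0, tolerance = 1e-12)
})

test_that("gamete frequencies stay normalized and a lost allele stays lost", {
  sc <- base_scenario()
  fm <- build_fitness_model(sc, "pyramid")
  st <- hw_state(0.05, 0)
  for (i in 1:200) {
    st <- step_generation(st, fm, 0.5)
    expect_lt(abs(sum(st$gamete) - 1), 1e-12)
  }
  expect_equal(unname(allele_freqs(st)["p2"]), 0)
})

test_that("zero mean fitness raises an extinction error, not NaN", {
  sc <- base_scenario(bt_locus = locus_spec("bt", 0.05, h = 0, w_ss = 0, w_rr = 0))
  fm <- build_fitness_model(sc, "bt")
  expect_error(step_generation(hw_state(0.05, 0), fm, 0), "extinct")
})

test_that("five generations match the 81-pair genotype enumeration oracle", {
  set.seed(42)
  for (rep in 1:12) {
    p1 <- runif(1); p2 <- runif(1)
    h1 <- runif(1); h2 <- runif(1)
    wss1 <- runif(1); wss2 <- runif(1)
    refuge <- runif(1, 0.05, 0.95)
    cost <- sample(c(0, runif(1, 0, 0.2)), 1)
    sc <- base_scenario(
      bt_locus = locus_spec("bt", p1, h = h1, w_ss = wss1),
      rnai_locus = locus_spec("rnai", p2, h = h2, w_ss = wss2),
      cost = cost_model(cost, if (cost > 0) "additive" else "none"),
      refuge_fraction = refuge
    )
    fm <- build_fitness_model(sc, "pyramid")
    st <- hw_state(p1, p2)
    G <- oracle_init(p1, p2)
    for (g in 1:5) {
      st <- step_generation(st, fm, refuge)
      G <- oracle_step(G, fm$w_transgenic, fm$w_refuge, refuge)
    }
    expect_equal(unname(genotype_freqs(st)), unname(G), tolerance = 1e-10)
  }
})

test_that("multiplicative fitness preserves linkage equilibrium and marginals", {
  sc <- base_scenario(bt_locus = locus_spec("bt", 0.05, h = 0.5, w_ss = 0.206),
                      rnai_locus = locus_spec("rnai", 0.01, h = 0.2, w_ss = 0.34))
  fm <- build_fitness_model(sc, "pyramid")
  # refuge 0 makes overall fitness exactly multiplicative across loci
  st <- hw_state(0.05, 0.01)
  p1 <- 0.05; p2 <- 0.01
  w1 <- single_locus_fitness(sc$bt_locus, c("ss", "rs", "rr"))
  w2 <- single_locus_fitness(sc$rnai_locus, c("ss", "rs", "rr"))
  for (g in 1:50) {
    st <- step_generation(st, fm, 0)
    expect_lt(abs(linkage_d(st)), 1e-12)
    p1 <- single_locus_next_p(p1, w1, 0)
    p2 <- single_locus_next_p(p2, w2, 0)
  }
  expect_equal(unname(allele_freqs(st)), c(p1, p2), tolerance = 1e-10)
})

test_that("population fitness is the genotype-weighted mean on transgenic cotton", {
  sc <- base_scenario(bt_locus = locus_spec("bt", 1, h = 0.5, w_ss = 0.206),
                      rnai_locus = locus_spec("rnai", 1, h = 0.5, w_ss = 0.34))
  fm <- build_fitness_model(sc, "pyramid")
  expect_equal(population_fitness(hw_state(1, 1), fm), 1)
  expect_equal(population_fitness(hw_state(0, 0), fm), 0.206 * 0.34)
  # HW population at p = 0.5, single locus, w = (0.2, 0.6, 1.0) -> 0.6
  sc2 <- base_scenario(bt_locus = locus_spec("bt", 0.5, h = 0.5, w_ss = 0.2))
  fm2 <- build_fitness_model(sc2, "bt")
  expect_equal(population_fitness(hw_state(0.5, 0), fm2), 0.6)
})

test_that("resistance already fixed is declared in the first year", {
  sc <- base_scenario(bt_locus = locus_spec("bt", 1, h = 0.5, w_ss = 0.206))
  sim <- time_to_resistance(sc, "bt_alone")
  expect_true(sim$reached)
  expect_equal(ceiling(sim$years_to_resistance), 1)
})

test_that("years to resistance are fractional in thirds of a year", {
  sc <- base_scenario()
  sim <- time_to_resistance(sc, "bt_alone")
  g <- sim$years_to_resistance * sc$generations_per_year
  expect_equal(g, round(g))
  expect_equal(max(sim$trajectory$generation), g)
  # threshold met at the final generation and not before
  pf <- sim$trajectory$pop_fitness
  expect_true(all(pf[-length(pf)] < 0.5) && pf[length(pf)] >= 0.5)
})

test_that("durability is monotone in refuge, dominance, init frequency and cost", {
  yrs <- function(sc, strategy = "bt_alone") {
    time_to_resistance(sc, strategy)$years_to_resistance
  }
  by_refuge <- vapply(c(0.05, 0.1, 0.25, 0.5),
                      function(r) yrs(base_scenario(refuge_fraction = r)),
                      numeric(1))
  expect_true(all(diff(by_refuge) >= 0))
  by_h <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(h) {
    yrs(base_scenario(bt_locus = locus_spec("bt", 0.05, h = h, w_ss = 0.206)))
  }, numeric(1))
  expect_true(all(diff(by_h) <= 0))
  by_p0 <- vapply(c(0.001, 0.01, 0.05, 0.2), function(p) {
    yrs(base_scenario(bt_locus = locus_spec("bt", p, h = 0.5, w_ss = 0.206)))
  }, numeric(1))
  expect_true(all(diff(by_p0) <= 0))
  by_cost <- vapply(c(0, 0.02, 0.05, 0.1), function(cc) {
    yrs(base_scenario(cost = cost_model(cc, "additive")))
  }, numeric(1))
  expect_true(all(diff(by_cost) >= 0))
})

test_that("a pyramid outlasts either single-trait cotton at equal locus parameters", {
  sc <- base_scenario(bt_locus = locus_spec("bt", 0.01, h = 0.5, w_ss = 0.25),
                      rnai_locus = locus_spec("rnai", 0.01, h = 0.5, w_ss = 0.25))
  t_pyr <- time_to_resistance(sc, "pyramid")$years_to_resistance
  t_bt <- time_to_resistance(sc, "bt_alone")$years_to_resistance
  t_rn <- time_to_resistance(sc, "rnai_alone")$years_to_resistance
  expect_gte(t_pyr, t_bt)
  expect_gte(t_pyr, t_rn)
})

test_that("sequence durability is the sum of its two phases", {
  sc <- base_scenario()
  t_bt <- time_to_resistance(sc, "bt_alone")$years_to_resistance
  t_rn <- time_to_resistance(sc, "rnai_alone")$years_to_resistance
  expect_equal(sequence_time(sc), t_bt + t_rn)
  # monotone in the RNAi initial frequency
  sc_hi <- base_scenario(rnai_locus = locus_spec("rnai", 0.01, h = 0.5, w_ss = 0.34))
  expect_lte(sequence_time(sc_hi), sequence_time(sc))
  # a phase that never reaches the threshold propagates as NA
  sc_never <- base_scenario(
    rnai_locus = locus_spec("rnai", 0, h = 0.5, w_ss = 0.34),
    max_years = 5
  )
  expect_true(is.na(sequence_time(sc_never)))
})

test_that("refuge_sweep tabulates and sweep_deltas pivots correctly", {
  sc <- base_scenario()
  one <- refuge_sweep(sc, refuges = 0.5, strategies = "bt_alone")
  expect_equal(nrow(one), 1)
  sw <- refuge_sweep(sc, refuges = c(0.05, 0.5))
  expect_equal(nrow(sw), 6)
  expect_equal(sw$delta_vs_bt_alone[sw$strategy == "bt_alone"], c(0, 0))
  d <- sweep_deltas(sw)
  expect_equal(nrow(d), 2)
  expect_equal(d$sequence_minus_bt_alone, d$sequence - d$bt_alone)
  expect_equal(d$pyramid_minus_sequence, d$pyramid - d$sequence)
})

test_that("scenario presets encode the three published parameterizations", {
  pre <- scenario_presets()
  expect_named(pre, c("realistic", "optimistic", "pessimistic"))
  expect_equal(pre$realistic$cost$mode, "none")
  expect_equal(pre$realistic$bt_locus$init_r_freq, 0.05)
  expect_equal(pre$realistic$rnai_locus$init_r_freq, 0.001)
  expect_equal(pre$realistic$bt_locus$h, 0.5)
  expect_equal(pre$optimistic$rnai_locus$h, 0.2)
  expect_equal(pre$optimistic$cost$mode, "additive")
  expect_equal(pre$optimistic$cost$cost_per_r_allele, 0.05)
  expect_equal(pre$pessimistic$rnai_locus$init_r_freq, 0.01)
  expect_equal(pre$pessimistic$bt_locus$w_ss, 1 - 0.794)
})

test_that("scenario files round-trip through flat YAML", {
  sc <- base_scenario(cost = cost_model(0.05, "additive"), name = "rt")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back$bt_locus$w_ss, sc$bt_locus$w_ss)
  expect_equal(back$cost$cost_per_r_allele, 0.05)
  expect_equal(back$refuge_fraction, sc$refuge_fraction)
  expect_equal(back$name, "rt")
})

test_that("selfed multi-heterozygotes yield (1/4)^n double homozygotes", {
  expect_equal(expected_double_homozygote_fraction(2), 1 / 16)
  expect_equal(expected_double_homozygote_fraction(1), 1 / 4)
  expect_equal(expected_double_homozygote_fraction(3), 1 / 64)
  expect_error(expected_double_homozygote_fraction(0), "positive integer")
})

test_that("simulation tidiers and autoplot expose the trajectory", {
  sim <- time_to_resistance(base_scenario(), "pyramid")
  tr <- tidy(sim)
  expect_named(tr, c("generation", "year", "p1", "p2", "D", "pop_fitness"))
  gl <- glance(sim)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$years_to_resistance, sim$years_to_resistance)
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(plot_durability(refuge_sweep(base_scenario(), refuges = 0.5)),
                  "ggplot")
})
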