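# Synthetic data generators.

test_that("the default design reproduces the study layout", {
  d <- generate_bioassay(bioassay_design(seed = 1))
  expect_equal(nrow(d), 2 * 7 * 2 * 3)
  expect_true(all(d$n_larvae == 50))
  expect_true(all(d$n_normal_pupae >= 0 & d$n_normal_pupae <= 50))
  expect_setequal(unique(d$cotton),
                  c("W0", "GFP", "Bt", "JHA", "JHB", "Bt+JHA", "Bt+JHB"))
})

test_that("identical seeds give identical datasets, different seeds differ", {
  a <- generate_bioassay(bioassay_design(seed = 7))
  b <- generate_bioassay(bioassay_design(seed = 7))
  c <- generate_bioassay(bioassay_design(seed = 8))
  expect_identical(a, b)
  expect_false(identical(a$n_normal_pupae, c$n_normal_pupae))
})

test_that("survival probability boundaries behave deterministically", {
  cells <- tidyr::expand_grid(strain = "SCD", cotton = c("W0", "Bt"))
  probs <- dplyr::mutate(cells, survival_prob = c(1, 0))
  des <- bioassay_design(strains = "SCD", cottons = c("W0", "Bt"),
                         survival_prob = probs, seed = 2)
  d <- generate_bioassay(des)
  expect_true(all(d$n_normal_pupae[d$cotton == "W0"] == d$n_larvae[d$cotton == "W0"]))
  expect_true(all(d$n_normal_pupae[d$cotton == "Bt"] == 0))
  expect_true(all(lengths(d$dev_times_days[d$cotton == "Bt"]) == 0))
})

test_that("development times stay inside the 14-30 day recording window", {
  d <- generate_bioassay(bioassay_design(seed = 3))
  all_times <- unlist(d$dev_times_days)
  expect_true(all(all_times >= 14 & all_times <= 30))
  expect_equal(lengths(d$dev_times_days), d$n_normal_pupae)
})

test_that("design validation rejects incomplete or invalid maps", {
  short <- tibble::tibble(strain = "SCD", cotton = "W0", survival_prob = 0.8)
  expect_error(bioassay_design(strains = c("SCD", "SCD-r1"),
                               survival_prob = short), "every strain x cotton")
  bad <- bioassay_design(seed = 1)$survival_prob
  bad$survival_prob[1] <- 1.4
  expect_error(bioassay_design(survival_prob = bad))
})

test_that("the generated survival frequencies recover the configured map", {
  # mean simulated efficacy of the Bt/SCD cell over 200 design repetitions
  # lands within 3 points of the configured efficacy
  des <- bioassay_design(seed = 1)
  cfg <- des$survival_prob
  p_bt <- cfg$survival_prob[cfg$strain == "SCD" & cfg$cotton == "Bt"]
  p_w0 <- cfg$survival_prob[cfg$strain == "SCD" & cfg$cotton == "W0"]
  configured_eff <- 100 * (1 - p_bt / p_w0)
  effs <- vapply(1:200, function(i) {
    d <- generate_bioassay(bioassay_design(
      strains = "SCD", cottons = c("W0", "Bt"), years = "2016", seed = 5000 + i
    ))
    e <- bioassay_efficacy(d)
    e$efficacy_pct[e$cotton == "Bt"]
  }, numeric(1))
  expect_lt(abs(mean(effs) - configured_eff), 3)
})

test_that("noiseless qPCR tables give exact configured folds", {
  q <- generate_qpcr(c(W0 = 1, GFP = 1, JHA = 0.3), n = 3, noise_sd = 0, seed = 4)
  folds <- relative_expression(q$ct_target, q$ct_reference)
  expect_equal(folds, rep(c(1, 1, 0.3), each = 3))
  q1 <- generate_qpcr(c(only = 0.25), n = 1, noise_sd = 0, seed = 4)
  expect_equal(relative_expression(q1$ct_target, q1$ct_reference), 0.25)
})

test_that("noisy qPCR group means recover configured folds within 10%", {
  q <- generate_qpcr(c(high = 1, low = 0.3), n = 20, noise_sd = 0.15, seed = 9)
  q$fold <- relative_expression(q$ct_target, q$ct_reference)
  means <- tapply(q$fold, q$group, mean)
  expect_lt(abs(means[["high"]] - 1) / 1, 0.1)
  expect_lt(abs(means[["low"]] - 0.3) / 0.3, 0.1)
})

test_that("transcript panels honour the planted-match manifest exactly", {
  p <- generate_transcript_panel(
    n_transcripts = 10, transcript_length = 500,
    planted = data.frame(transcript = c(2, 5, 9), length = c(21, 25, 30)),
    seed = 13
  )
  res <- screen_fragment(p$fragment, p$panel, k = 21)
  expect_equal(sum(res$summary$flagged), 3)
  expect_setequal(res$summary$subject_id[res$summary$flagged],
                  p$manifest$transcript_id)
  m <- dplyr::arrange(res$matches, .data$subject_id)
  mf <- dplyr::arrange(p$manifest, .data$transcript_id)
  expect_equal(m$subject_id, mf$transcript_id)
  expect_equal(m$length, mf$length)
  expect_equal(m$query_start, mf$fragment_start)
  expect_equal(m$subject_start, mf$transcript_start)
  # count identity on the 30-nt block: 30 - 21 + 1 = 10 windows
  expect_equal(m$n_windows[m$length == 30], 10L)
})

test_that("unplanted panels screen clean across seeds", {
  clean <- vapply(1:20, function(s) {
    p <- generate_transcript_panel(n_transcripts = 5, transcript_length = 400,
                                   seed = s)
    screen_fragment(p$fragment, p$panel, k = 21)$verdict == "clean"
  }, logical(1))
  expect_gte(mean(clean), 0.99)
})

test_that("planted blocks longer than their transcript are rejected", {
  expect_error(
    generate_transcript_panel(n_transcripts = 2, transcript_length = 40,
                              planted = data.frame(transcript = 1, length = 60),
                              fragment_length = 100, seed = 1),
    "longer than"
  )
})
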