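small_cfg <- function(seed = 1, ...) {
  cohort_config(n_participants = 6, seed = seed, ...)
}

test_that("the default design produces 33 participants with four sessions each", {
  co <- generate_cohort(cohort_config(seed = 1))
  expect_equal(dplyr::n_distinct(co$decisions$participant_id), 33)
  per <- dplyr::count(co$decisions, participant_id, session_id)
  expect_equal(dplyr::n_distinct(per$session_id), 4)
  expect_true(all(per$n == 21))  # 18 redistribution + 3 lottery rounds
  expect_setequal(unique(co$decisions$session_id),
                  c("voi_voting", "voi_dictatorship",
                    "informed_voting", "informed_dictatorship"))
  # behind the veil the condition never reveals the class
  voi <- dplyr::filter(co$decisions, info_type == "voi")
  expect_true(all(voi$condition == "voi"))
})

test_that("generation is deterministic given the seed and leaves the global RNG alone", {
  withr::with_seed(99, rng_before <- runif(1))
  co1 <- generate_cohort(small_cfg(seed = 5))
  co2 <- generate_cohort(small_cfg(seed = 5))
  expect_identical(co1$decisions, co2$decisions)
  expect_identical(co1$affect, co2$affect)
  expect_identical(co1$incomes, co2$incomes)
  expect_identical(co1$neural, co2$neural)
  co3 <- generate_cohort(small_cfg(seed = 6))
  expect_false(identical(co1$decisions, co3$decisions))
})

test_that("voting sessions cover every (class, societal outcome) pair", {
  co <- generate_cohort(small_cfg(seed = 2))
  voting <- dplyr::filter(co$decisions, session_type == "voting", !is_lottery)
  cov <- dplyr::count(voting, participant_id, session_id,
                      assigned_class, society_rule)
  # the structured block guarantees every cell of the 3 x 3 grid at least once
  expect_true(all(cov$n >= 1))
  pairs_per_session <- dplyr::count(cov, participant_id, session_id)
  expect_true(all(pairs_per_session$n == 9))
  rounds <- dplyr::count(voting, participant_id, session_id)
  expect_true(all(rounds$n == 18))
})

test_that("payoffs and income bookkeeping are consistent", {
  co <- generate_cohort(small_cfg(seed = 3))
  sch <- co$config$scheme
  non_lot <- dplyr::filter(co$decisions, !is_lottery)
  expect_equal(non_lot$payoff,
               payoff(sch, non_lot$society_rule, non_lot$assigned_class))
  # each participant's total equals the sum of their per-round payoffs
  self_tot <- dplyr::filter(co$incomes, player == "self")
  by_hand <- dplyr::summarise(
    dplyr::group_by(co$decisions, participant_id, session_id),
    total = sum(payoff), .groups = "drop")
  joined <- dplyr::left_join(self_tot, by_hand,
                             by = c("participant_id", "session_id"))
  expect_equal(joined$total_income, joined$total)
})

test_that("structural constraints on the configuration are enforced", {
  expect_error(cohort_config(rounds_per_session = 6),
               class = "voigame_config_error")
  expect_error(cohort_config(policy = list(nonsense = 1)),
               class = "voigame_config_error")
  expect_error(cohort_config(neural = list(noise_sd = -1)))
})

test_that("dictatorship sessions split rounds between self and partner dictators", {
  co <- generate_cohort(small_cfg(seed = 4))
  dict <- dplyr::filter(co$decisions, session_type == "dictatorship",
                        !is_lottery)
  counts <- dplyr::count(dict, participant_id, session_id, decider)
  self_n <- dplyr::filter(counts, decider == "self_dictator")
  expect_true(all(self_n$n == 6))  # a third of eighteen rounds
  # a self-dictated round always enacts the participant's own choice
  self_rounds <- dplyr::filter(dict, decider == "self_dictator")
  expect_equal(self_rounds$society_rule, self_rounds$chosen_rule)
  expect_false(any(dict$decider == "vote"))
})

test_that("the default policy mixture lands the veil non-equality share in a plausible band", {
  shares <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(seed = 100 + s))
    voi <- dplyr::filter(co$decisions, condition == "voi", !is_lottery)
    mean(voi$chosen_rule != "equality")
  }, numeric(1))
  # sanity band around the observed behavioural rate of 72.3%
  expect_gt(mean(shares), 0.623)
  expect_lt(mean(shares), 0.823)
})

test_that("neural outcomes follow the generative model", {
  co <- generate_cohort(small_cfg(seed = 8))
  att <- co$sessions

  # null model: all coefficients zero, unit noise
  null_tab <- withr::with_seed(21, generate_neural(
    co$decisions, att, list(noise_sd = 1)))
  cells <- cell_means(null_tab)
  expect_true(all(abs(cells$ybar) <= 4 / sqrt(cells$n)))

  # pure interaction, no noise: the veil cell difference is exactly a + c
  det_tab <- withr::with_seed(22, generate_neural(
    co$decisions, att, list(a = 0.5, c = 1, noise_sd = 0)))
  voi <- dplyr::filter(det_tab, condition == "voi")
  diff <- mean(voi$outcome[voi$chosen_rule == "equality"]) -
    mean(voi$outcome[voi$chosen_rule != "equality"])
  expect_equal(diff, 1.5)

  # negative income slope induces a negative outcome correlation
  slope_tab <- withr::with_seed(23, generate_neural(
    co$decisions, att, list(s = -1, noise_sd = 0.01)))
  ve <- dplyr::left_join(
    dplyr::filter(slope_tab, condition == "voi", chosen_rule == "equality"),
    att, by = c("participant_id", "session_id"))
  expect_lt(cor(ve$relative_income, ve$outcome), 0)
})
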