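toy_decisions <- function() {
  # one participant with 9 veil rounds choosing equality 3 times, another
  # always selfish
  tibble::tibble(
    participant_id = rep(c("p1", "p2"), each = 9),
    condition = "voi",
    chosen_rule = c(rep("equality", 3), rep("inequality", 6),
                    rep("inequality", 9)),
    is_lottery = FALSE)
}

test_that("choice proportions aggregate per participant then across", {
  s <- choice_proportion_summary(toy_decisions(), "voi", "equality")
  expect_equal(sort(s$per_participant$value), c(0, 1 / 3))
  expect_equal(s$mean, 1 / 6)
  expect_equal(s$sem, sd(c(0, 1 / 3)) / sqrt(2))
  # complement: proportions over a partition of the rules sum to one
  s2 <- choice_proportion_summary(toy_decisions(), "voi",
                                  c("inequality", "intermediate"))
  expect_equal(s$mean + s2$mean, 1)
  all_selfish <- dplyr::mutate(toy_decisions(), chosen_rule = "inequality")
  s3 <- choice_proportion_summary(all_selfish, "voi", "inequality")
  expect_equal(s3$mean, 1)
  expect_equal(s3$sem, 0)
})

test_that("ever-chose proportions match direct enumeration with binomial dispersion", {
  co <- generate_cohort(cohort_config(n_participants = 8, seed = 41))
  s <- ever_chose_summary(co$decisions, "voi", "equality")
  # brute-force enumeration oracle
  voi <- co$decisions[co$decisions$condition == "voi" &
                        !co$decisions$is_lottery, ]
  ever <- tapply(voi$chosen_rule, voi$participant_id,
                 function(r) any(r == "equality"))
  expect_equal(s$mean, mean(ever))
  expect_equal(s$sem, sqrt(mean(ever) * (1 - mean(ever)) / length(ever)))
  none <- dplyr::mutate(toy_decisions(), chosen_rule = "inequality")
  expect_equal(ever_chose_summary(none, "voi", "equality")$mean, 0)
})

test_that("participants without qualifying trials are dropped with a warning", {
  d <- toy_decisions()
  d$condition[d$participant_id == "p2"] <- "high"
  expect_warning(s <- choice_proportion_summary(d, "voi", "equality"),
                 "p2")
  expect_equal(s$n, 1)
})

test_that("group mean comparison matches the textbook Welch formula", {
  x <- c(1, 2, 3); expect_equal(group_mean_test(x, x)$statistic, 0)
  expect_equal(group_mean_test(x, x)$p_value, 1)
  withr::with_seed(51, {
    a <- rnorm(12, 1, 2); b <- rnorm(9, 0, 1)
    got <- group_mean_test(a, b)
    want <- oracle_welch(a, b)
    expect_equal(got$statistic, want$t)
    expect_equal(got$p_value, want$p)
    # near-complete separation drives p towards zero
    sep <- group_mean_test(rnorm(6, 0, 1e-3), 1 + rnorm(6, 0, 1e-3))
    expect_lt(sep$p_value, 1e-6)
  })
  expect_error(group_mean_test(1, c(1, 2)))
})

test_that("the 2x2 chi-squared matches the closed-form statistic", {
  m <- matrix(c(6, 2, 13, 29), nrow = 2)  # attitude x gender counts
  got <- chi2_2x2(m)
  expect_equal(got$statistic, oracle_chi2_2x2(m), tolerance = 1e-10)
  expect_equal(got$statistic, 5.5340, tolerance = 1e-4)
  # Yates correction shrinks the statistic
  expect_lt(chi2_2x2(m, correct = TRUE)$statistic, got$statistic)
  expect_equal(chi2_2x2(matrix(c(5, 5, 5, 5), 2))$statistic, 0)
  expect_equal(chi2_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  # proportional rows are independent
  expect_equal(chi2_2x2(matrix(c(10, 20, 30, 60), 2))$statistic, 0)
  expect_error(chi2_2x2(matrix(c(0, 0, 3, 4), 2)),
               class = "voigame_zero_marginal_error")
  expect_error(chi2_2x2(matrix(c(1.5, 1, 1, 1), 2)))
})

test_that("pearson correlation matches the covariance formula", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$estimate, 1)
  withr::with_seed(52, {
    a <- rnorm(30); b <- 0.3 * a + rnorm(30)
    got <- pearson_r(a, b)
    expect_equal(got$estimate, oracle_pearson(a, b))
    expect_equal(got$p_value, cor.test(a, b)$p.value)
  })
  expect_error(pearson_r(rep(1, 5), 1:5),
               class = "voigame_constant_input_error")
  expect_error(pearson_r(1:2, 1:2))
})

test_that("cluster bootstrap resamples whole participants deterministically", {
  d <- tibble::tibble(participant_id = rep(sprintf("p%d", 1:5), each = 4),
                      y = rep(c(1, 2, 3, 4, 5), each = 4))
  # identical rows within clusters, statistic insensitive to which clusters:
  same <- tibble::tibble(participant_id = rep(sprintf("p%d", 1:5), each = 4),
                         y = 2)
  b0 <- cluster_bootstrap(same, function(dd) mean(dd$y), B = 100, seed = 1)
  expect_true(all(b0$replicates == b0$estimate))
  expect_equal(b0$ci_lower, b0$ci_upper)

  b1 <- cluster_bootstrap(d, function(dd) mean(dd$y), B = 150, seed = 9)
  b2 <- cluster_bootstrap(d, function(dd) mean(dd$y), B = 150, seed = 9)
  expect_identical(b1$replicates, b2$replicates)
  expect_true(b1$ci_lower <= b1$ci_upper)

  # no replicate ever contains a partial participant
  integrity <- cluster_bootstrap(d, function(dd) {
    sizes <- table(dd$participant_id)
    if (any(sizes %% 4 != 0)) stop("partial cluster")
    mean(dd$y)
  }, B = 100, seed = 2)
  expect_equal(integrity$n_failures, 0L)
})

test_that("failing replicates are redrawn up to the retry bound", {
  d <- tibble::tibble(participant_id = rep(sprintf("p%d", 1:5), each = 2),
                      y = 1:10)
  # fails whenever the first cluster is absent from the resample
  flaky <- function(dd) {
    if (!"p1" %in% dd$participant_id) stop("cluster p1 missing")
    mean(dd$y)
  }
  res <- cluster_bootstrap(d, flaky, B = 100, seed = 3, max_failures = 1000)
  expect_gt(res$n_failures, 0)
  expect_length(res$replicates, 100)
  # succeeds on the observed data but fails on (almost) every resample,
  # which contains duplicated clusters
  no_dupes <- function(dd) {
    if (any(table(dd$participant_id) > 2)) stop("duplicated cluster")
    mean(dd$y)
  }
  expect_error(
    cluster_bootstrap(d, no_dupes, B = 100, seed = 4, max_failures = 5),
    "more than 5")
})
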