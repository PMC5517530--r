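fixture_table <- function() {
  tab <- tidyr::expand_grid(
    condition = c("voi", "high", "middle", "low"),
    rule = c("inequality", "intermediate", "equality"))
  tab$ybar <- c(0.2, 0.1, 0.5, 1.0, 0.3, -0.2, 0, 0, 0.1, -0.3, 0.4, 0.2)
  tab$n <- c(50L, 30L, 20L, 25L, 10L, 5L, 12L, 12L, 16L, 8L, 14L, 18L)
  structure(tab, class = c("cell_table", class(tab)))
}

test_that("decision categories follow class interest", {
  expect_equal(
    decision_category(
      c("voi", "voi", "high", "high", "low", "low", "middle"),
      c("equality", "inequality", "intermediate", "inequality",
        "inequality", "equality", "equality")),
    c("equality_selfless", "non_equality_selfish", "equality_selfless",
      "non_equality_selfish", "equality_selfless", "non_equality_selfish",
      "neutral"))
})

get_cell_pub <- function(cells, cond, rule, what) {
  cells[[what]][cells$condition == cond & cells$rule == rule]
}

test_that("cell means aggregate per-trial records with counts", {
  d <- tibble::tibble(condition = c("voi", "voi", "high"),
                      chosen_rule = c("equality", "equality", "inequality"),
                      outcome = c(2, 4, 1))
  cells <- cell_means(d)
  expect_equal(get_cell_pub(cells, "voi", "equality", "ybar"), 3)
  expect_equal(get_cell_pub(cells, "voi", "equality", "n"), 2L)
  expect_error(tau(cells, c("voi", "equality"), c("high", "equality")),
               class = "voigame_empty_cell_error")
})

test_that("participant-first aggregation averages participant means", {
  d <- tibble::tibble(
    participant_id = c("a", "a", "a", "b"),
    condition = "voi", chosen_rule = "equality",
    outcome = c(0, 0, 3, 5))
  pooled <- cell_means(d)
  byp <- cell_means(d, participant = "participant_id")
  expect_equal(pooled$ybar, 2)
  expect_equal(byp$ybar, 3)    # mean of participant means (1 and 5)
  expect_equal(byp$n, 4L)      # counts stay trial counts for the weights
})

test_that("the fixture table reproduces hand-computed estimators and the exact identity", {
  tab <- fixture_table()
  dec <- decompose_interaction(tab, c("voi", "equality"),
                               c("high", "inequality"))
  expect_equal(dec$tau, -0.5)
  expect_equal(dec$psi_condition, -0.2177272727, tolerance = 1e-9)
  expect_equal(dec$psi_rule, 0.0111111111, tolerance = 1e-9)
  expect_equal(dec$pi, -0.2933838384, tolerance = 1e-9)
  expect_identical(dec$pi, dec$tau - dec$psi_condition - dec$psi_rule)
})

test_that("estimators match the literal brute-force transcription on random tables", {
  withr::with_seed(17, {
    for (i in 1:200) {
      tab <- random_cell_table()
      t1 <- sample(c("voi", "high", "middle", "low"), 2)
      r1 <- sample(c("inequality", "intermediate", "equality"), 2)
      dec <- decompose_interaction(tab, c(t1[1], r1[1]), c(t1[2], r1[2]))
      expect_equal(dec$tau, oracle_tau(tab, t1[1], r1[1], t1[2], r1[2]),
                   tolerance = 1e-12)
      expect_equal(dec$psi_condition, oracle_psi_condition(tab, t1[1], t1[2]),
                   tolerance = 1e-12)
      expect_equal(dec$psi_rule, oracle_psi_rule(tab, r1[1], r1[2]),
                   tolerance = 1e-12)
      expect_equal(dec$pi, oracle_pi(tab, t1[1], r1[1], t1[2], r1[2]),
                   tolerance = 1e-12)
    }
  })
})

test_that("additive tables have zero interaction and constants shift nothing", {
  withr::with_seed(18, {
    for (i in 1:50) {
      tab <- random_cell_table()
      f <- rnorm(4); names(f) <- c("voi", "high", "middle", "low")
      g <- rnorm(3); names(g) <- c("inequality", "intermediate", "equality")
      tab$ybar <- f[tab$condition] + g[tab$rule]
      dec <- decompose_interaction(tab, c("voi", "equality"),
                                   c("high", "inequality"))
      expect_lt(abs(dec$pi), 1e-10)

      # shift invariance on an arbitrary (non-additive) table
      tab2 <- random_cell_table()
      shift <- rnorm(1, sd = 10)
      tab2s <- tab2
      tab2s$ybar <- tab2$ybar + shift
      d0 <- decompose_interaction(tab2, c("voi", "equality"),
                                  c("low", "intermediate"))
      d1 <- decompose_interaction(tab2s, c("voi", "equality"),
                                  c("low", "intermediate"))
      expect_equal(d1$tau, d0$tau, tolerance = 1e-10)
      expect_equal(d1$psi_condition, d0$psi_condition, tolerance = 1e-10)
      expect_equal(d1$psi_rule, d0$psi_rule, tolerance = 1e-10)
      expect_equal(d1$pi, d0$pi, tolerance = 1e-10)
    }
  })
})

test_that("tidy and glance expose the four estimators", {
  dec <- decompose_interaction(fixture_table(), c("voi", "equality"),
                               c("high", "inequality"))
  td <- tidy(dec)
  expect_equal(td$term, c("tau", "psi_condition", "psi_rule", "pi"))
  gl <- glance(dec)
  expect_equal(gl$pi, dec$pi)
  expect_equal(gl$n_trials, sum(fixture_table()$n))
})
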