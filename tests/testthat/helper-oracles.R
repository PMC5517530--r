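# Independent brute-force oracles: literal term-by-term transcriptions of the
# decomposition estimators and textbook statistic formulas, kept deliberately
# separate from the package's vectorised implementations.

oracle_lookup <- function(tab, cond, rule, what = "ybar") {
  tab[[what]][tab$condition == cond & tab$rule == rule]
}

oracle_tau <- function(tab, c1, r1, c0, r0) {
  oracle_lookup(tab, c1, r1) - oracle_lookup(tab, c0, r0)
}

oracle_psi_condition <- function(tab, c1, c0) {
  n_ineq <- sum(tab$n[tab$rule == "inequality"])
  n_int <- sum(tab$n[tab$rule == "intermediate"])
  n_eq <- sum(tab$n[tab$rule == "equality"])
  tot <- n_ineq + n_int + n_eq
  (oracle_lookup(tab, c1, "inequality") - oracle_lookup(tab, c0, "inequality")) * (n_ineq / tot) +
    (oracle_lookup(tab, c1, "intermediate") - oracle_lookup(tab, c0, "intermediate")) * (n_int / tot) +
    (oracle_lookup(tab, c1, "equality") - oracle_lookup(tab, c0, "equality")) * (n_eq / tot)
}

# sums over high, low and voi; the middle condition is left out
oracle_psi_rule <- function(tab, r1, r0) {
  n_high <- sum(tab$n[tab$condition == "high"])
  n_low <- sum(tab$n[tab$condition == "low"])
  n_voi <- sum(tab$n[tab$condition == "voi"])
  tot <- n_high + n_low + n_voi
  (oracle_lookup(tab, "high", r1) - oracle_lookup(tab, "high", r0)) * (n_high / tot) +
    (oracle_lookup(tab, "low", r1) - oracle_lookup(tab, "low", r0)) * (n_low / tot) +
    (oracle_lookup(tab, "voi", r1) - oracle_lookup(tab, "voi", r0)) * (n_voi / tot)
}

oracle_pi <- function(tab, c1, r1, c0, r0) {
  oracle_tau(tab, c1, r1, c0, r0) -
    oracle_psi_condition(tab, c1, c0) -
    oracle_psi_rule(tab, r1, r0)
}

# a fully populated random 4 x 3 cell table
random_cell_table <- function() {
  tab <- tidyr::expand_grid(condition = c("voi", "high", "middle", "low"),
                            rule = c("inequality", "intermediate", "equality"))
  tab$n <- sample(1:50, nrow(tab), replace = TRUE)
  tab$ybar <- rnorm(nrow(tab), sd = 2)
  structure(tab, class = c("cell_table", class(tab)))
}

# random payoff scheme satisfying the equality feasibility constraint
random_feasible_scheme <- function() {
  h <- runif(1, 1500, 4000)
  m <- runif(1, 900, h - 100)
  cost <- runif(1, 0, 0.6)
  l <- m - (1 - cost) * (h - m)
  if (l <= 0) return(random_feasible_scheme())
  payoff_scheme(h, m, l, cost_rate = cost,
                intermediate_fraction = runif(1, 0.2, 0.8))
}

# textbook Welch t statistic and two-tailed p
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Pearson chi-squared for a 2x2 via N(ad - bc)^2 / (row and column products)
oracle_chi2_2x2 <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  N <- sum(m)
  N * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# Pearson r from the covariance formula
oracle_pearson <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) / (sd(x) * sd(y)) *
    length(x) / (length(x) - 1)
}
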