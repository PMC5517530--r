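#' Softmax-utility agent policy
#'
#' A generative stand-in for the two motivators debated for equality choices:
#' consideration of others and prospective calculation for oneself. An agent
#' scores each rule by a weighted utility
#' `u(rule) = w_self * own(rule) + w_total * total(rule) - w_fair * spread(rule)`
#' and chooses with softmax probability `exp(u / temperature)` (normalised).
#'
#' The own-payoff term depends on what the agent knows. In an Informed
#' condition it is the payoff of the agent's class. Behind the veil of
#' ignorance (VoI) the class is hidden, and the `risk` switch decides how the
#' agent summarises it: `"expected_value"` uses the mean payoff across the
#' three classes (a risk-neutral prospective calculation), `"maximin"` uses
#' the minimum class payoff (maximise the worst foreseen payoff).
#'
#' @param w_self Weight on the own-payoff term. Default 1.
#' @param w_total Weight on the total society payout. Default 0.
#' @param w_fair Weight on the (negative) payoff spread `max - min`; positive
#'   values favour more equal rules. Default 0.
#' @param risk `"expected_value"` or `"maximin"`; only matters behind the VoI.
#' @param temperature Softmax temperature in money points, > 0. Small values
#'   approach the argmax rule; large values approach uniform choice. Default
#'   150.
#' @return An object of class `agent_policy`.
#' @examples
#' choice_distribution(agent_policy(risk = "maximin"), "voi", payoff_scheme())
#' @export
agent_policy <- function(w_self = 1, w_total = 0, w_fair = 0,
                         risk = c("expected_value", "maximin"),
                         temperature = 150) {
  risk <- match.arg(risk)
  stopifnot(is.finite(w_self), is.finite(w_total), is.finite(w_fair))
  if (!(is.numeric(temperature) && temperature > 0)) {
    abort("`temperature` must be > 0")
  }
  structure(list(w_self = w_self, w_total = w_total, w_fair = w_fair,
                 risk = risk, temperature = temperature),
            class = "agent_policy")
}

#' @export
print.agent_policy <- function(x, ...) {
  cat(sprintf("<agent_policy> w_self=%g w_total=%g w_fair=%g risk=%s temperature=%g\n",
              x$w_self, x$w_total, x$w_fair, x$risk, x$temperature))
  invisible(x)
}

#' Choice probabilities of a policy in a condition
#'
#' @param policy An [agent_policy()].
#' @param condition `"voi"` or an informed class condition (`"high"`,
#'   `"middle"`, `"low"`).
#' @param scheme A [payoff_scheme()].
#' @return A tibble with columns `rule` and `prob` (three rows, probabilities
#'   summing to 1).
#' @export
choice_distribution <- function(policy, condition, scheme) {
  stopifnot(inherits(policy, "agent_policy"), inherits(scheme, "payoff_scheme"))
  condition <- match_levels(condition, condition_levels(), "condition")
  stopifnot(length(condition) == 1)
  rules <- rule_levels()
  pay <- vapply(rules, function(r) payoff(scheme, r, class_levels()),
                numeric(3))  # 3 classes x 3 rules
  own <- if (condition == "voi") {
    switch(policy$risk,
           expected_value = colMeans(pay),
           maximin = apply(pay, 2, min))
  } else {
    pay[match(condition, class_levels()), ]
  }
  spread <- apply(pay, 2, max) - apply(pay, 2, min)
  total <- vapply(rules, function(r) total_payout(scheme, r), numeric(1))
  u <- policy$w_self * own + policy$w_total * total - policy$w_fair * spread
  z <- u / policy$temperature
  p <- exp(z - max(z))
  tibble::tibble(rule = rules, prob = unname(p / sum(p)))
}

# Draw one rule from a policy's choice distribution (uses the current RNG
# stream).
sample_choice <- function(policy, condition, scheme) {
  d <- choice_distribution(policy, condition, scheme)
  d$rule[[sample.int(3L, 1L, prob = d$prob)]]
}
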