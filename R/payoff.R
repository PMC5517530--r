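#' Construct a redistribution payoff scheme
#'
#' A society of three income classes (high, middle, low) plays under one of
#' three redistribution rules. The `inequality` rule preserves the pre-tax
#' incomes; the `equality` rule transfers `T = h - m` away from the high
#' class, of which a fraction `cost_rate` is lost as a deadweight cost and the
#' remainder reaches the low class; the `intermediate` rule transfers
#' `intermediate_fraction * T` in the same way. The middle class is never
#' taxed and never receives a transfer, so its payoff is rule-invariant.
#'
#' Absolute equality is only attainable when the post-transfer incomes line
#' up, i.e. when `m - l == (1 - cost_rate) * (h - m)`. Parameter sets that
#' violate this feasibility constraint are rejected, because the resulting
#' "equality" rule would not actually equalise payoffs.
#'
#' @param h,m,l Pre-tax incomes of the high, middle and low class, in abstract
#'   money points; must satisfy `h > m > l > 0`.
#' @param cost_rate Fraction of any transferred amount lost as a deadweight
#'   cost, in `[0, 1)`. Default 0.25.
#' @param intermediate_fraction Fraction of the full transfer `T` moved under
#'   the intermediate rule, in `(0, 1)`. Default 0.5.
#'
#' @return An object of class `payoff_scheme`: a list with elements `h`, `m`,
#'   `l`, `cost_rate`, `transfer_T`, `intermediate_fraction`.
#'
#' @examples
#' sch <- payoff_scheme(2100, 1300, 700)
#' payoff_table(sch)
#' @export
payoff_scheme <- function(h = 2100, m = 1300, l = 700, cost_rate = 0.25,
                          intermediate_fraction = 0.5) {
  stopifnot(is.numeric(h), is.numeric(m), is.numeric(l),
            length(h) == 1, length(m) == 1, length(l) == 1)
  if (!(h > m && m > l && l > 0)) {
    abort(
      sprintf("pre-tax incomes must satisfy h > m > l > 0 (got h=%g, m=%g, l=%g)",
              h, m, l),
      class = "voigame_ordering_error"
    )
  }
  if (!(cost_rate >= 0 && cost_rate < 1)) {
    abort("`cost_rate` must lie in [0, 1)", class = "voigame_ordering_error")
  }
  if (!(intermediate_fraction > 0 && intermediate_fraction < 1)) {
    abort("`intermediate_fraction` must lie in (0, 1)")
  }
  T_full <- h - m
  # feasibility: equality must actually equalise all three payoffs
  if (abs((m - l) - (1 - cost_rate) * T_full) > 1e-8 * max(h, 1)) {
    abort(
      sprintf(paste0(
        "infeasible equality rule: requires m - l == (1 - cost_rate) * (h - m), ",
        "i.e. %g == %g"), m - l, (1 - cost_rate) * T_full),
      class = "voigame_infeasible_equality_error"
    )
  }
  structure(
    list(h = h, m = m, l = l, cost_rate = cost_rate, transfer_T = T_full,
         intermediate_fraction = intermediate_fraction),
    class = "payoff_scheme"
  )
}

#' @export
print.payoff_scheme <- function(x, ...) {
  cat("<payoff_scheme>\n")
  cat(sprintf("  pre-tax incomes: high %g, middle %g, low %g\n", x$h, x$m, x$l))
  cat(sprintf("  transfer T = %g, cost rate = %g, intermediate fraction = %g\n",
              x$transfer_T, x$cost_rate, x$intermediate_fraction))
  print(payoff_table(x))
  invisible(x)
}

transfer_amount <- function(scheme, rule) {
  frac <- c(inequality = 0,
            intermediate = scheme$intermediate_fraction,
            equality = 1)[rule]
  unname(frac) * scheme$transfer_T
}

#' Payoff of a class under a rule
#'
#' Vectorised over `rule` and `cls` (recycled to a common length).
#'
#' @param scheme A [payoff_scheme()].
#' @param rule Character vector of rules (`"inequality"`, `"intermediate"`,
#'   `"equality"`).
#' @param cls Character vector of classes (`"high"`, `"middle"`, `"low"`).
#' @return Numeric vector of payoffs in money points.
#' @examples
#' payoff(payoff_scheme(), "equality", c("high", "middle", "low"))
#' @export
payoff <- function(scheme, rule, cls) {
  stopifnot(inherits(scheme, "payoff_scheme"))
  rule <- match_levels(rule, rule_levels(), "rule")
  cls <- match_levels(cls, class_levels(), "class")
  n <- max(length(rule), length(cls))
  rule <- rep_len(rule, n)
  cls <- rep_len(cls, n)
  tr <- transfer_amount(scheme, rule)
  base <- c(high = scheme$h, middle = scheme$m, low = scheme$l)[cls]
  delta <- ifelse(cls == "high", -tr,
                  ifelse(cls == "low", (1 - scheme$cost_rate) * tr, 0))
  unname(base + delta)
}

#' All payoffs of a scheme as a tibble
#'
#' @param scheme A [payoff_scheme()].
#' @return A tibble with columns `rule`, `class`, `payoff` (9 rows).
#' @export
payoff_table <- function(scheme) {
  grid <- tidyr::expand_grid(rule = rule_levels(), class = class_levels())
  grid$payoff <- payoff(scheme, grid$rule, grid$class)
  grid
}

#' Total society payout under a rule
#'
#' The endowment `h + m + l` minus the deadweight cost (`cost_rate` times the
#' transferred amount). The inequality rule conserves the endowment exactly.
#'
#' @inheritParams payoff
#' @return Numeric vector of total payouts.
#' @export
total_payout <- function(scheme, rule) {
  stopifnot(inherits(scheme, "payoff_scheme"))
  rule <- match_levels(rule, rule_levels(), "rule")
  scheme$h + scheme$m + scheme$l - scheme$cost_rate * transfer_amount(scheme, rule)
}

#' Society-level rule determination
#'
#' In voting mode the strict majority rule wins; split votes (all three votes
#' distinct) are resolved by a uniform random draw among the cast votes. In
#' dictatorship mode the dictator's choice is adopted.
#'
#' @param choices Character vector of chosen rules, one per player (exactly
#'   three in voting mode).
#' @param mode `"voting"` or `"dictatorship"`.
#' @param dictator_index Index into `choices` of the dictator; required in
#'   dictatorship mode.
#' @return A single rule.
#' @examples
#' society_decision(c("equality", "equality", "inequality"), "voting")
#' @export
society_decision <- function(choices, mode = c("voting", "dictatorship"),
                             dictator_index = NULL) {
  mode <- match.arg(mode)
  choices <- match_levels(choices, rule_levels(), "rule")
  if (mode == "dictatorship") {
    if (is.null(dictator_index)) {
      abort("`dictator_index` is required in dictatorship mode",
            class = "voigame_missing_dictator_error")
    }
    return(choices[[dictator_index]])
  }
  if (length(choices) != 3L) {
    abort("voting mode requires exactly three choices")
  }
  tab <- table(choices)
  if (max(tab) >= 2L) {
    return(names(tab)[which.max(tab)])
  }
  # split vote: uniform among the cast votes
  choices[[sample.int(3L, 1L)]]
}

match_levels <- function(x, levels, what) {
  x <- as.character(x)
  bad <- !(x %in% levels)
  if (any(bad)) {
    abort(sprintf("invalid %s value(s): %s (expected one of %s)",
                  what, paste(unique(x[bad]), collapse = ", "),
                  paste(levels, collapse = ", ")),
          class = "voigame_level_error")
  }
  x
}
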