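#' Categorise a decision relative to the decider's interest
#'
#' Behind the veil of ignorance the equality rule is the equality decision
#' and the other rules are non-equality decisions. In the informed
#' conditions the categorisation is relative to class interest: for the high
#' class, intermediate and equality are selfless and inequality is selfish;
#' for the low class, inequality and intermediate are selfless and equality
#' (which pays the low class the most) is selfish. All middle-class
#' decisions are neutral, since the middle payoff is rule-invariant.
#'
#' @param condition Character vector of conditions.
#' @param chosen_rule Character vector of rules.
#' @return Character vector: `"equality_selfless"`,
#'   `"non_equality_selfish"` or `"neutral"`.
#' @export
decision_category <- function(condition, chosen_rule) {
  condition <- match_levels(condition, condition_levels(), "condition")
  chosen_rule <- match_levels(chosen_rule, rule_levels(), "rule")
  dplyr::case_when(
    condition == "middle" ~ "neutral",
    condition == "voi" & chosen_rule == "equality" ~ "equality_selfless",
    condition == "voi" ~ "non_equality_selfish",
    condition == "high" & chosen_rule != "inequality" ~ "equality_selfless",
    condition == "high" ~ "non_equality_selfish",
    condition == "low" & chosen_rule != "equality" ~ "equality_selfless",
    TRUE ~ "non_equality_selfish")
}

#' Cell means of a condition-by-rule table
#'
#' Aggregates per-trial outcomes into the 4 x 3 (condition x rule) cell
#' table consumed by the interaction decomposition: per-cell mean outcome
#' and trial count. With `participant` set, cells are aggregated
#' participant-first (mean of participant means), which mirrors a
#' second-level analysis that averages within subjects before comparing
#' across them; cell counts remain trial counts either way, since the
#' frequency weights of the decomposition are observed choice frequencies.
#'
#' @param data Tibble of per-trial records.
#' @param outcome,condition,rule Column names (strings) of the outcome
#'   value, condition and rule.
#' @param participant Optional column name for participant-first averaging.
#' @return A `cell_table`: tibble with columns `condition`, `rule`, `n`,
#'   `ybar`.
#' @examples
#' cells <- cell_means(
#'   tibble::tibble(condition = c("voi", "voi"), rule = "equality",
#'                  y = c(2, 4)),
#'   outcome = "y", condition = "condition", rule = "rule")
#' @export
cell_means <- function(data, outcome = "outcome", condition = "condition",
                       rule = "chosen_rule", participant = NULL) {
  stopifnot(all(c(outcome, condition, rule) %in% names(data)))
  d <- tibble::tibble(condition = data[[condition]], rule = data[[rule]],
                      y = data[[outcome]])
  if (!is.null(participant)) {
    d$participant <- data[[participant]]
    per <- dplyr::summarise(
      dplyr::group_by(d, .data$condition, .data$rule, .data$participant),
      m = mean(.data$y), k = dplyr::n(), .groups = "drop")
    out <- dplyr::summarise(
      dplyr::group_by(per, .data$condition, .data$rule),
      n = as.integer(sum(.data$k)), ybar = mean(.data$m), .groups = "drop")
  } else {
    out <- dplyr::summarise(
      dplyr::group_by(d, .data$condition, .data$rule),
      n = dplyr::n(), ybar = mean(.data$y), .groups = "drop")
  }
  structure(out, class = c("cell_table", class(out)))
}

get_cell <- function(table, condition, rule, what = "ybar") {
  i <- which(table$condition == condition & table$rule == rule)
  if (length(i) == 0) {
    abort(sprintf("empty cell: no trials with condition '%s' and rule '%s'",
                  condition, rule),
          class = "voigame_empty_cell_error")
  }
  table[[what]][[i]]
}

# Observed-frequency weights over exactly `set`, normalised to sum to 1.
freq_weights <- function(table, margin = c("rule", "condition"), set) {
  margin <- match.arg(margin)
  counts <- vapply(set, function(v)
    sum(table$n[table[[margin]] == v]), numeric(1))
  if (sum(counts) == 0) abort("no trials in the weighting categories")
  counts / sum(counts)
}

#' Average treatment combination effect
#'
#' The difference of cell means between a target (condition, rule) cell and
#' a baseline cell.
#'
#' @param table A [cell_means()] table.
#' @param target,baseline Length-2 character vectors `c(condition, rule)`.
#' @return A single number.
#' @export
tau <- function(table, target, baseline) {
  get_cell(table, target[[1]], target[[2]]) -
    get_cell(table, baseline[[1]], baseline[[2]])
}

#' Average marginal effect of a condition
#'
#' The per-rule differences between two conditions, weighted by the observed
#' frequency of each of the three rule choices (pooled trial counts,
#' normalised over the three rules).
#'
#' @param table A [cell_means()] table.
#' @param c1,c0 Target and baseline condition.
#' @return A single number.
#' @export
psi_condition <- function(table, c1, c0) {
  rules <- rule_levels()
  w <- freq_weights(table, "rule", rules)
  diffs <- vapply(rules, function(r)
    get_cell(table, c1, r) - get_cell(table, c0, r), numeric(1))
  sum(w * diffs)
}

#' Average marginal effect of a rule
#'
#' The per-condition differences between two rules, weighted by the observed
#' condition frequencies. The middle condition is excluded from both the sum
#' and the weight normalisation: middle-class decisions are neutral (the
#' payoff is rule-invariant there), so the marginal rule effect is averaged
#' over the high, low and veil-of-ignorance conditions only.
#'
#' @param table A [cell_means()] table.
#' @param r1,r0 Target and baseline rule.
#' @return A single number.
#' @export
psi_rule <- function(table, r1, r0) {
  conds <- intersect(condition_levels(), unique(table$condition))
  conds <- setdiff(conds, "middle")
  w <- freq_weights(table, "condition", conds)
  diffs <- vapply(conds, function(cc)
    get_cell(table, cc, r1) - get_cell(table, cc, r0), numeric(1))
  sum(w * diffs)
}

#' Baseline-invariant decomposition of an interaction effect
#'
#' Decomposes the combined effect of moving from a baseline (condition,
#' rule) cell to a target cell into the marginal effect of the condition,
#' the marginal effect of the rule, and the remaining interaction:
#' \deqn{\pi = \tau - \psi_{condition} - \psi_{rule}.}
#' The identity holds exactly by construction. In a purely additive table
#' (`ybar = f(condition) + g(rule)`) the interaction \eqn{\pi} is zero for
#' every contrast, and all four quantities are invariant to adding a
#' constant to every cell — which is what makes the decomposition
#' independent of the baseline activity level.
#'
#' @param table A [cell_means()] table.
#' @param target,baseline Length-2 character vectors `c(condition, rule)`,
#'   e.g. `c("voi", "equality")` against `c("high", "inequality")`.
#' @return An object of class `voi_decomposition` with elements `tau`,
#'   `psi_condition`, `psi_rule`, `pi`, `target`, `baseline`, `cells`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 8, seed = 3))
#' cells <- cell_means(dplyr::left_join(
#'   cohort$neural, dplyr::select(cohort$decisions, "participant_id",
#'                                "session_id", "round_index", "is_lottery"),
#'   by = c("participant_id", "session_id", "round_index")))
#' decompose_interaction(cells, c("voi", "equality"), c("high", "inequality"))
#' @export
decompose_interaction <- function(table, target = c("voi", "equality"),
                                  baseline = c("high", "inequality")) {
  t_ <- tau(table, target, baseline)
  psi_c <- psi_condition(table, target[[1]], baseline[[1]])
  psi_r <- psi_rule(table, target[[2]], baseline[[2]])
  structure(list(tau = t_, psi_condition = psi_c, psi_rule = psi_r,
                 pi = t_ - psi_c - psi_r,
                 target = target, baseline = baseline, cells = table),
            class = "voi_decomposition")
}

#' @export
print.voi_decomposition <- function(x, ...) {
  cat(sprintf("<voi_decomposition> (%s, %s) vs (%s, %s)\n",
              x$target[[1]], x$target[[2]], x$baseline[[1]], x$baseline[[2]]))
  cat(sprintf("  tau = %.4f  psi(condition) = %.4f  psi(rule) = %.4f  pi = %.4f\n",
              x$tau, x$psi_condition, x$psi_rule, x$pi))
  invisible(x)
}

#' @rdname decompose_interaction
#' @param x A `voi_decomposition`.
#' @param ... Unused.
#' @export
tidy.voi_decomposition <- function(x, ...) {
  tibble::tibble(
    term = c("tau", "psi_condition", "psi_rule", "pi"),
    estimate = c(x$tau, x$psi_condition, x$psi_rule, x$pi))
}

#' @rdname decompose_interaction
#' @export
glance.voi_decomposition <- function(x, ...) {
  tibble::tibble(
    target = paste(x$target, collapse = ":"),
    baseline = paste(x$baseline, collapse = ":"),
    tau = x$tau, psi_condition = x$psi_condition, psi_rule = x$psi_rule,
    pi = x$pi, n_trials = sum(x$cells$n))
}
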