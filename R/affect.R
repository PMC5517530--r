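#' Affective changes from the three thermometer ratings
#'
#' Feelings toward each partner are rated on a 0-100 feeling thermometer
#' before play (I), after play (II) and after the disclosure of total incomes
#' (III). The change after playing is `II - I`; the change after income
#' disclosure is `III - II`.
#'
#' @param rating_I,rating_II,rating_III Numeric vectors of thermometer
#'   degrees in `[0, 100]` (recycled to a common length).
#' @return A tibble with columns `delta_play` and `delta_disclosure`.
#' @examples
#' affective_changes(47.3, 57.7, 42.1)
#' @export
affective_changes <- function(rating_I, rating_II, rating_III) {
  for (r in list(rating_I, rating_II, rating_III)) {
    if (any(r < 0 | r > 100, na.rm = TRUE)) {
      abort("thermometer ratings must lie in [0, 100]",
            class = "voigame_rating_range_error")
    }
  }
  tibble::tibble(delta_play = rating_II - rating_I,
                 delta_disclosure = rating_III - rating_II)
}

#' Relative income
#'
#' A participant's accumulated income divided by that of the partners. Since
#' incomes were unrealised until the end of play, this ratio acts as an
#' expected reward during decisions. The denominator is the sum of the
#' partners' totals by default; `"mean"` divides by their average instead
#' (the two differ by a constant factor, so correlations are unaffected).
#'
#' @param participant_total Numeric vector of participant totals (>= 0).
#' @param partner_totals Partners' totals: a numeric vector (the partners of
#'   a single case) or a matrix/data frame with one row per case.
#' @param denominator `"sum"` (default) or `"mean"`.
#' @return Numeric vector of dimensionless ratios.
#' @examples
#' relative_income(900, c(600, 600))
#' @export
relative_income <- function(participant_total, partner_totals,
                            denominator = c("sum", "mean")) {
  denominator <- match.arg(denominator)
  if (is.data.frame(partner_totals)) partner_totals <- as.matrix(partner_totals)
  if (!is.matrix(partner_totals)) {
    partner_totals <- matrix(partner_totals, nrow = 1)
  }
  stopifnot(all(participant_total >= 0), all(partner_totals >= 0))
  denom <- rowSums(partner_totals)
  if (denominator == "mean") denom <- denom / ncol(partner_totals)
  if (any(denom <= 0)) {
    abort("partners' total income must be positive",
          class = "voigame_zero_denominator_error")
  }
  unname(participant_total / denom)
}

#' Build the participant-partner-session case table
#'
#' One case is a participant-partner-session triple: its three thermometer
#' ratings, the participant's and that partner's accumulated incomes, the
#' two affective changes, which side of the income comparison the
#' participant is on, and the attitude label from [classify_attitude()].
#'
#' @param affect Affect tibble with `participant_id`, `session_id`,
#'   `partner_id`, `rating_I`, `rating_II`, `rating_III` (e.g.
#'   `generate_cohort(...)$affect`).
#' @param incomes Long income tibble with `participant_id`, `session_id`,
#'   `player` (`"self"`, `"partner1"`, `"partner2"`) and `total_income`.
#' @return A tibble of labelled cases.
#' @export
attitude_cases <- function(affect, incomes) {
  self_tot <- dplyr::filter(incomes, .data$player == "self")
  self_tot <- dplyr::select(self_tot, "participant_id", "session_id",
                            participant_total = "total_income")
  partner_tot <- dplyr::filter(incomes, .data$player != "self")
  partner_tot <- dplyr::select(partner_tot, "participant_id", "session_id",
                               partner_id = "player",
                               partner_total = "total_income")
  cases <- dplyr::left_join(affect, self_tot,
                            by = c("participant_id", "session_id"))
  cases <- dplyr::left_join(cases, partner_tot,
                            by = c("participant_id", "session_id", "partner_id"))
  cases <- dplyr::bind_cols(
    cases, affective_changes(cases$rating_I, cases$rating_II, cases$rating_III))
  cases$income_side <- dplyr::case_when(
    cases$participant_total > cases$partner_total ~ "higher",
    cases$participant_total < cases$partner_total ~ "lower",
    TRUE ~ "equal")
  classify_attitude(cases)
}

#' Classify the accordance / non-accordance attitude
#'
#' Only cases in which the participant earned a *higher* income than the
#' partner are in scope. Among those, a decrease in affection after income
#' disclosure (`delta_disclosure < 0`) is unexpected from the material
#' vantage and marks an attitude of *accordance* with others; an increase
#' marks *non-accordance*; exactly zero change is excluded. Lower-income and
#' tied cases are labelled out of scope.
#'
#' @param cases A tibble with columns `delta_disclosure` and `income_side`
#'   (as built by [attitude_cases()]).
#' @return `cases` with a `label` column: `"accordance"`,
#'   `"non_accordance"`, `"excluded_zero"` or `"out_of_scope"`.
#' @export
classify_attitude <- function(cases) {
  stopifnot(all(c("delta_disclosure", "income_side") %in% names(cases)))
  cases$label <- dplyr::case_when(
    cases$income_side != "higher" ~ "out_of_scope",
    cases$delta_disclosure < 0 ~ "accordance",
    cases$delta_disclosure > 0 ~ "non_accordance",
    TRUE ~ "excluded_zero")
  cases
}

#' Apply the exclusion rules with full accounting
#'
#' Starting from the higher-income cases, removes (1) cases with exactly
#' zero affective change after disclosure and (2) contradictory sessions in
#' which the participant showed the accordance attitude to one partner but
#' the non-accordance attitude to the other; both pair-cases of a
#' contradictory session are dropped. Every filter stage is counted so the
#' screen is auditable. Whether a "contradictory case" counts sessions or
#' pair-cases is ambiguous in common usage, so the report exposes both.
#'
#' @param cases A labelled case tibble from [attitude_cases()] or
#'   [classify_attitude()].
#' @return An object of class `attitude_screen`: list with `retained` (the
#'   surviving cases), `excluded` (dropped higher-income cases with a
#'   `reason` column) and `accounting` (one-row tibble of stage counts:
#'   `n_cases`, `n_higher_income`, `n_zero_change`,
#'   `n_contradictory_sessions`, `n_contradictory_cases`, `n_retained`,
#'   `n_accordance`, `n_non_accordance`).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 6, seed = 2))
#' screen <- apply_exclusions(attitude_cases(cohort$affect, cohort$incomes))
#' glance(screen)
#' @export
apply_exclusions <- function(cases) {
  stopifnot("label" %in% names(cases))
  higher <- dplyr::filter(cases, .data$income_side == "higher")
  zero <- dplyr::filter(higher, .data$label == "excluded_zero")
  labelled <- dplyr::filter(higher,
                            .data$label %in% c("accordance", "non_accordance"))
  contradictory_key <- dplyr::summarise(
    dplyr::group_by(labelled, .data$participant_id, .data$session_id),
    contradictory = dplyr::n_distinct(.data$label) > 1, .groups = "drop")
  labelled <- dplyr::left_join(
    labelled, contradictory_key, by = c("participant_id", "session_id"))
  contra <- dplyr::filter(labelled, .data$contradictory)
  retained <- dplyr::select(dplyr::filter(labelled, !.data$contradictory),
                            -"contradictory")
  excluded <- dplyr::bind_rows(
    dplyr::mutate(zero, reason = "zero_change"),
    dplyr::mutate(dplyr::select(contra, -"contradictory"),
                  reason = "contradictory_session"))
  accounting <- tibble::tibble(
    n_cases = nrow(cases),
    n_higher_income = nrow(higher),
    n_zero_change = nrow(zero),
    n_contradictory_sessions = sum(contradictory_key$contradictory),
    n_contradictory_cases = nrow(contra),
    n_retained = nrow(retained),
    n_accordance = sum(retained$label == "accordance"),
    n_non_accordance = sum(retained$label == "non_accordance"))
  structure(list(retained = retained, excluded = excluded,
                 accounting = accounting),
            class = "attitude_screen")
}

#' @export
print.attitude_screen <- function(x, ...) {
  a <- x$accounting
  cat("<attitude_screen>\n")
  cat(sprintf("  %d cases, %d with higher income than the partner\n",
              a$n_cases, a$n_higher_income))
  cat(sprintf("  excluded: %d zero-change, %d pair-cases from %d contradictory session(s)\n",
              a$n_zero_change, a$n_contradictory_cases,
              a$n_contradictory_sessions))
  cat(sprintf("  retained: %d (%d accordance, %d non-accordance)\n",
              a$n_retained, a$n_accordance, a$n_non_accordance))
  invisible(x)
}

#' @rdname apply_exclusions
#' @param x An `attitude_screen`.
#' @param ... Unused.
#' @export
tidy.attitude_screen <- function(x, ...) x$retained

#' @rdname apply_exclusions
#' @export
glance.attitude_screen <- function(x, ...) x$accounting
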