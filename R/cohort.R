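#' Configuration of a synthetic cohort
#'
#' Bundles every parameter of the synthetic dataset generator: the design
#' (participants, sessions, rounds, lottery insertions, dictator share), the
#' agent policy mixture, the affect-rating generator and the trial-level
#' neural-outcome generator. Defaults reproduce the study design: 33
#' participants, a 2 x 2 session design (veil-of-ignorance/informed x
#' voting/dictatorship), 18 redistribution rounds per session of which a
#' structured block covers every (class, societal outcome) pair, randomly
#' inserted lottery rounds, and a dictator share of one third within
#' dictatorship sessions.
#'
#' @param n_participants Number of participants. Default 33.
#' @param rounds_per_session Redistribution rounds per session; must be >= 9
#'   so that every (class, societal outcome) pair can be covered in voting
#'   sessions. Default 18.
#' @param n_lottery Lottery rounds randomly inserted per session. Default 3.
#' @param dictator_fraction Share of rounds within a dictatorship session in
#'   which the participant (rather than a partner) dictates the societal
#'   rule. Default 1/3.
#' @param scheme A [payoff_scheme()].
#' @param policy Named list of policy-mixture parameters: `maximin_share`
#'   (probability that a simulated agent uses maximin rather than
#'   expected-value risk handling), and `w_self`, `w_total`, `w_fair`,
#'   `temperature` passed to [agent_policy()].
#' @param affect Named list of affect-generator parameters:
#'   `baseline_mean`, `baseline_sd` (feeling-thermometer rating I, degrees on
#'   the 0-100 scale), `play_effect` and `play_sd` (latent-attitude shift and
#'   noise of the change after playing), `disclosure_effect` and
#'   `disclosure_sd` (shift and noise of the change after income disclosure;
#'   the shift's sign is reversed relative to the play shift),
#'   `zero_change_prob` (probability of exactly zero change after
#'   disclosure), `income_slope` (slope linking relative income to the
#'   disclosure change; negative by default), `p_accordance` (probability of
#'   a latent accordance attitude per session) and `attitude_concordance`
#'   (probability that a partner-level attitude copies the session-level
#'   latent attitude; values < 1 let contradictory sessions arise).
#' @param neural Named list of trial-level outcome parameters `mu`, `a`, `b`,
#'   `c`, `d`, `s`, `ranef_sd`, `noise_sd`; see [generate_neural()].
#' @param seed Integer seed making the whole dataset reproducible.
#'
#' @return An object of class `cohort_config` (a named list).
#' @export
cohort_config <- function(n_participants = 33,
                          rounds_per_session = 18,
                          n_lottery = 3,
                          dictator_fraction = 1 / 3,
                          scheme = payoff_scheme(),
                          policy = list(),
                          affect = list(),
                          neural = list(),
                          seed = 1L) {
  policy_def <- list(maximin_share = 0.1, w_self = 1, w_total = 0,
                     w_fair = 0, temperature = 240)
  affect_def <- list(baseline_mean = 46, baseline_sd = 12,
                     play_effect = 12, play_sd = 6,
                     disclosure_effect = 15, disclosure_sd = 6,
                     zero_change_prob = 24 / 78, income_slope = -100,
                     p_accordance = 0.38, attitude_concordance = 0.9)
  neural_def <- list(mu = 0.1, a = 0.15, b = -0.1, c = 0.4, d = 0.25,
                     s = -5, ranef_sd = 0.2, noise_sd = 0.8)
  policy <- merge_params(policy_def, policy, "policy")
  affect <- merge_params(affect_def, affect, "affect")
  neural <- merge_params(neural_def, neural, "neural")

  stopifnot(inherits(scheme, "payoff_scheme"))
  if (n_participants < 1) abort("`n_participants` must be positive")
  if (rounds_per_session < 9) {
    abort(paste("`rounds_per_session` must be >= 9 so each (class, societal",
                "outcome) pair can occur in voting sessions"),
          class = "voigame_config_error")
  }
  if (n_lottery < 0) abort("`n_lottery` must be non-negative")
  stopifnot(dictator_fraction >= 0, dictator_fraction <= 1,
            affect$zero_change_prob >= 0, affect$zero_change_prob <= 1,
            affect$p_accordance >= 0, affect$p_accordance <= 1,
            affect$attitude_concordance >= 0, affect$attitude_concordance <= 1,
            neural$noise_sd >= 0, neural$ranef_sd >= 0)

  structure(list(n_participants = as.integer(n_participants),
                 rounds_per_session = as.integer(rounds_per_session),
                 n_lottery = as.integer(n_lottery),
                 dictator_fraction = dictator_fraction,
                 scheme = scheme, policy = policy, affect = affect,
                 neural = neural, seed = as.integer(seed)),
            class = "cohort_config")
}

merge_params <- function(defaults, user, what) {
  if (length(user) == 0) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown %s parameter(s): %s", what,
                  paste(unknown, collapse = ", ")),
          class = "voigame_config_error")
  }
  utils::modifyList(defaults, user)
}

session_grid <- function() {
  tidyr::expand_grid(info_type = c("voi", "informed"),
                     session_type = c("voting", "dictatorship"))
}

#' Generate a full synthetic cohort
#'
#' Simulates the complete dataset the downstream analyses consume: per-round
#' decision records, feeling-thermometer affect ratings (I, II, III per
#' partner per session), accumulated total incomes for the participant and
#' both simulated partners, and trial-level neural outcomes. The simulation
#' is deterministic given `config$seed`.
#'
#' Societal outcomes in voting sessions traverse the full 3 x 3 grid of
#' (assigned class, societal rule) in random order, so every participant
#' experiences every combination — the rounds are scripted, as in a
#' deception design with simulated partners. In dictatorship sessions the
#' societal rule is whatever the round's dictator (the participant in
#' roughly `dictator_fraction` of rounds, a simulated partner otherwise)
#' chooses, so coverage there is incidental.
#'
#' @param config A [cohort_config()].
#' @return An object of class `voi_cohort`: a list of tibbles `decisions`,
#'   `affect`, `incomes`, `neural`, plus `sessions` (per-session generator
#'   ground truth: latent session attitude and realised relative income)
#'   and the `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 4, seed = 7))
#' dplyr::count(cohort$decisions, condition)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  sessions <- session_grid()
  decisions <- vector("list", config$n_participants)
  pair_rows <- vector("list", config$n_participants)
  # agents share all policy weights and differ only in risk handling, so the
  # eight (risk x condition) choice distributions can be computed once
  dist_cache <- choice_cache(config$policy, config$scheme)

  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("p%02d", p)
    self_policy <- draw_cached_policy(config$policy, dist_cache)
    partner_policies <- list(draw_cached_policy(config$policy, dist_cache),
                             draw_cached_policy(config$policy, dist_cache))
    ses_dec <- vector("list", nrow(sessions))
    ses_pair <- vector("list", nrow(sessions))
    for (s in seq_len(nrow(sessions))) {
      info <- sessions$info_type[[s]]
      stype <- sessions$session_type[[s]]
      sid <- paste(info, stype, sep = "_")
      ses_dec[[s]] <- simulate_session(pid, sid, info, stype, self_policy,
                                       partner_policies, config)
      # latent attitudes: session-level draw, partner-level copies with
      # probability attitude_concordance
      latent <- runif(1) < config$affect$p_accordance
      flip <- runif(2) >= config$affect$attitude_concordance
      ses_pair[[s]] <- tibble::tibble(
        participant_id = pid, session_id = sid,
        partner_id = c("partner1", "partner2"),
        latent_attitude = ifelse(xor(latent, flip), "accordance",
                                 "non_accordance"),
        session_accordance = latent)
    }
    decisions[[p]] <- dplyr::bind_rows(ses_dec)
    pair_rows[[p]] <- dplyr::bind_rows(ses_pair)
  }
  decisions <- dplyr::bind_rows(decisions)
  pairs <- dplyr::bind_rows(pair_rows)

  incomes <- accumulate_incomes(decisions)
  affect <- generate_affect(pairs, incomes, config$affect)

  session_attitudes <- dplyr::left_join(
    dplyr::distinct(pairs, .data$participant_id, .data$session_id,
                    .data$session_accordance),
    session_relative_income(incomes),
    by = c("participant_id", "session_id"))
  neural <- generate_neural(decisions, session_attitudes, config$neural)

  structure(list(decisions = decisions,
                 affect = dplyr::select(affect, -"session_accordance"),
                 incomes = incomes, neural = neural,
                 sessions = session_attitudes, config = config),
            class = "voi_cohort")
}

draw_policy <- function(pp) {
  risk <- if (runif(1) < pp$maximin_share) "maximin" else "expected_value"
  agent_policy(w_self = pp$w_self, w_total = pp$w_total, w_fair = pp$w_fair,
               risk = risk, temperature = pp$temperature)
}

choice_cache <- function(pp, scheme) {
  cache <- list()
  for (risk in c("expected_value", "maximin")) {
    pol <- agent_policy(w_self = pp$w_self, w_total = pp$w_total,
                        w_fair = pp$w_fair, risk = risk,
                        temperature = pp$temperature)
    cache[[risk]] <- lapply(stats::setNames(nm = condition_levels()),
                            function(cond)
                              choice_distribution(pol, cond, scheme)$prob)
  }
  cache
}

draw_cached_policy <- function(pp, cache) {
  risk <- if (runif(1) < pp$maximin_share) "maximin" else "expected_value"
  list(risk = risk, cache = cache)
}

# draw one rule from a cached (risk, condition) distribution
cached_choice <- function(policy, condition) {
  rule_levels()[[sample.int(3L, 1L, prob = policy$cache[[policy$risk]][[condition]])]]
}

simulate_session <- function(pid, sid, info, stype, self_policy,
                             partner_policies, config) {
  n_r <- config$rounds_per_session
  scheme <- config$scheme
  # structured class x societal-outcome grid; extra rounds drawn uniformly
  grid <- tidyr::expand_grid(cls = class_levels(), outcome = rule_levels())
  if (n_r > 9) {
    extra <- tibble::tibble(cls = sample(class_levels(), n_r - 9, TRUE),
                            outcome = sample(rule_levels(), n_r - 9, TRUE))
    grid <- dplyr::bind_rows(grid, extra)
  }
  grid <- grid[sample.int(n_r), ]

  condition <- if (info == "voi") rep("voi", n_r) else grid$cls
  chosen <- vapply(condition, function(cond)
    cached_choice(self_policy, cond), character(1), USE.NAMES = FALSE)

  # the two simulated partners fill the remaining two classes at random
  swap <- runif(n_r) < 0.5
  others <- t(vapply(grid$cls, function(cl) setdiff(class_levels(), cl),
                     character(2)))
  p1_cls <- ifelse(swap, others[, 2], others[, 1])
  p2_cls <- ifelse(swap, others[, 1], others[, 2])

  if (stype == "voting") {
    decider <- rep("vote", n_r)
    society <- grid$outcome
  } else {
    n_self <- max(1L, round(config$dictator_fraction * n_r))
    self_rounds <- sample.int(n_r, n_self)
    decider <- ifelse(seq_len(n_r) %in% self_rounds,
                      "self_dictator", "partner_dictator")
    society <- character(n_r)
    for (i in seq_len(n_r)) {
      if (decider[[i]] == "self_dictator") {
        society[[i]] <- society_decision(
          c(chosen[[i]], "inequality", "inequality"),
          mode = "dictatorship", dictator_index = 1L)
      } else {
        # a partner dictator decides from its own class (informed sessions)
        # or behind the veil
        k <- sample.int(2L, 1L)
        partner_cls <- if (k == 1L) p1_cls[[i]] else p2_cls[[i]]
        cond <- if (info == "voi") "voi" else partner_cls
        society[[i]] <- cached_choice(partner_policies[[k]], cond)
      }
    }
  }

  rounds <- tibble::tibble(
    participant_id = pid, session_id = sid, session_type = stype,
    info_type = info, condition = condition, assigned_class = grid$cls,
    chosen_rule = chosen, society_rule = society, decider = decider,
    payoff = payoff(scheme, society, grid$cls),
    partner1_class = p1_cls, partner2_class = p2_cls,
    partner1_payoff = payoff(scheme, society, p1_cls),
    partner2_payoff = payoff(scheme, society, p2_cls),
    is_lottery = FALSE)

  if (config$n_lottery > 0) {
    n_l <- config$n_lottery
    lot_rule <- vapply(seq_len(n_l), function(i)
      cached_choice(self_policy, "voi"), character(1))
    lot_cls <- sample(class_levels(), n_l, TRUE)
    # partners draw their own lotteries, keeping accumulated totals
    # comparable across the three players
    lp <- lapply(partner_policies, function(pol) {
      r <- vapply(seq_len(n_l), function(i)
        cached_choice(pol, "voi"), character(1))
      payoff(scheme, r, sample(class_levels(), n_l, TRUE))
    })
    lottery <- tibble::tibble(
      participant_id = pid, session_id = sid, session_type = stype,
      info_type = info, condition = "voi", assigned_class = lot_cls,
      chosen_rule = lot_rule, society_rule = lot_rule,
      decider = "self_dictator",
      payoff = payoff(scheme, lot_rule, lot_cls),
      partner1_class = NA_character_, partner2_class = NA_character_,
      partner1_payoff = lp[[1]], partner2_payoff = lp[[2]],
      is_lottery = TRUE)
    rounds <- dplyr::bind_rows(rounds, lottery)
  }
  rounds <- rounds[sample.int(nrow(rounds)), ]
  rounds$round_index <- seq_len(nrow(rounds))
  dplyr::relocate(rounds, "round_index", .after = "info_type")
}

accumulate_incomes <- function(decisions) {
  per <- dplyr::group_by(decisions, .data$participant_id, .data$session_id)
  per <- dplyr::summarise(per,
                          self = sum(.data$payoff),
                          partner1 = sum(.data$partner1_payoff),
                          partner2 = sum(.data$partner2_payoff),
                          .groups = "drop")
  tidyr::pivot_longer(per, c("self", "partner1", "partner2"),
                      names_to = "player", values_to = "total_income")
}

session_relative_income <- function(incomes, denominator = c("sum", "mean")) {
  denominator <- match.arg(denominator)
  wide <- tidyr::pivot_wider(incomes, names_from = "player",
                             values_from = "total_income")
  denom <- wide$partner1 + wide$partner2
  if (denominator == "mean") denom <- denom / 2
  tibble::tibble(participant_id = wide$participant_id,
                 session_id = wide$session_id,
                 relative_income = wide$self / denom)
}

generate_affect <- function(pairs, incomes, ap) {
  rel <- session_relative_income(incomes)
  af <- dplyr::left_join(pairs, rel, by = c("participant_id", "session_id"))
  n <- nrow(af)
  sign <- ifelse(af$latent_attitude == "accordance", 1, -1)
  I <- clip01(rnorm(n, ap$baseline_mean, ap$baseline_sd))
  d_play <- sign * ap$play_effect + rnorm(n, 0, ap$play_sd)
  II <- clip01(I + d_play)
  zero <- runif(n) < ap$zero_change_prob
  # relative income is self / (partner1 + partner2), so the fair share is
  # 1/2; the slope acts on the deviation from it
  d_disc <- -sign * ap$disclosure_effect +
    ap$income_slope * (af$relative_income - 0.5) +
    rnorm(n, 0, ap$disclosure_sd)
  III <- ifelse(zero, II, clip01(II + d_disc))
  af$rating_I <- I
  af$rating_II <- II
  af$rating_III <- III
  dplyr::select(af, -"relative_income")
}

clip01 <- function(x) pmin(pmax(x, 0), 100)

#' Generate trial-level neural outcomes
#'
#' Produces one continuous outcome per non-lottery decision trial, emulating
#' a region-of-interest percent-signal-change series from which the lottery
#' baseline has already been subtracted. The generative model is
#' \deqn{y = \mu + a\,1[\mathrm{equality\ or\ selfless}] + b\,1[\mathrm{VoI}]
#'   + c\,1[\mathrm{equality} \wedge \mathrm{VoI}\ \mathrm{or\ selfless}
#'   \wedge \mathrm{Informed}] + d\,1[\mathrm{accordance}]
#'   + s\,(\mathrm{rel} - 1/2) \cdot 1[\mathrm{equality} \wedge \mathrm{VoI}]
#'   + u_{participant} + \varepsilon}
#' with participant random effects `u ~ N(0, ranef_sd^2)` and noise
#' `\eqn{\varepsilon} ~ N(0, noise_sd^2)`. `c` is the designed
#' condition-by-decision interaction; `s` links the outcome to relative
#' income on equality-behind-the-veil trials. `rel` is the session's
#' relative income (own total over the sum of both partners' totals);
#' centring it at the fair share 1/2 keeps the `s` term from shifting the
#' (VoI, equality) cell mean, so it adds slope structure without masking
#' the interaction.
#'
#' @param decisions Decisions tibble (as produced by [generate_cohort()]);
#'   lottery rounds are dropped.
#' @param session_attitudes Tibble with one row per participant-session:
#'   `participant_id`, `session_id`, `session_accordance` (logical),
#'   `relative_income`.
#' @param params Named list with elements `mu`, `a`, `b`, `c`, `d`, `s`,
#'   `ranef_sd`, `noise_sd`.
#' @return Tibble with columns `participant_id`, `session_id`,
#'   `round_index`, `condition`, `chosen_rule`, `outcome`.
#' @export
generate_neural <- function(decisions, session_attitudes, params) {
  params <- merge_params(list(mu = 0, a = 0, b = 0, c = 0, d = 0, s = 0,
                              ranef_sd = 0, noise_sd = 1), params, "neural")
  d <- dplyr::filter(decisions, !.data$is_lottery)
  d <- dplyr::left_join(
    d, session_attitudes, by = c("participant_id", "session_id"))
  cat_ <- decision_category(d$condition, d$chosen_rule)
  ind_a <- d$chosen_rule == "equality" | cat_ == "equality_selfless"
  ind_c <- cat_ == "equality_selfless"
  ind_voi <- d$condition == "voi"
  ind_s <- ind_voi & d$chosen_rule == "equality"
  pids <- unique(d$participant_id)
  u <- rnorm(length(pids), 0, params$ranef_sd)
  names(u) <- pids
  y <- params$mu + params$a * ind_a + params$b * ind_voi +
    params$c * ind_c + params$d * as.numeric(d$session_accordance) +
    params$s * (d$relative_income - 0.5) * ind_s +
    u[d$participant_id] + rnorm(nrow(d), 0, params$noise_sd)
  tibble::tibble(participant_id = d$participant_id,
                 session_id = d$session_id, round_index = d$round_index,
                 condition = d$condition, chosen_rule = d$chosen_rule,
                 outcome = unname(y))
}

#' @export
print.voi_cohort <- function(x, ...) {
  cat("<voi_cohort>\n")
  cat(sprintf("  %d participants, %d decision rows (%d lottery), %d affect cases\n",
              dplyr::n_distinct(x$decisions$participant_id),
              nrow(x$decisions), sum(x$decisions$is_lottery),
              nrow(x$affect)))
  cat(sprintf("  seed %d\n", x$config$seed))
  invisible(x)
}
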