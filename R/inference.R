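#' Rules counted as selfless / equality in a condition
#'
#' Behind the veil of ignorance the comparison is equality vs non-equality;
#' in the informed high and low conditions it is selfless vs selfish
#' relative to class interest (see [decision_category()]).
#'
#' @param condition One of `"voi"`, `"high"`, `"low"`.
#' @return Character vector of rules.
#' @export
selfless_rules <- function(condition) {
  switch(match_levels(condition, c("voi", "high", "low"), "condition"),
         voi = "equality",
         high = c("intermediate", "equality"),
         low = c("inequality", "intermediate"))
}

#' @rdname selfless_rules
#' @export
selfish_rules <- function(condition) {
  setdiff(rule_levels(), selfless_rules(condition))
}

#' Per-participant choice proportions in a condition
#'
#' For each participant, the proportion of non-lottery trials of the given
#' condition in which a rule from `rule_set` was chosen, summarised as mean
#' +/- s.e.m. across participants. Participants without qualifying trials
#' are dropped with a warning.
#'
#' @param decisions Decisions tibble (with `participant_id`, `condition`,
#'   `chosen_rule`, `is_lottery`).
#' @param condition The condition to restrict to.
#' @param rule_set Character vector of rules counted as a hit, e.g.
#'   [selfless_rules()].
#' @return A `proportion_summary`: list with `per_participant` (tibble of
#'   `participant_id`, `value`) and the across-participant `mean`, `sem`,
#'   `n`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 6, seed = 4))
#' choice_proportion_summary(cohort$decisions, "voi", selfless_rules("voi"))
#' @export
choice_proportion_summary <- function(decisions, condition, rule_set) {
  per <- participant_values(
    decisions, condition,
    function(rules) mean(rules %in% rule_set))
  new_proportion_summary(per, condition, rule_set,
                         statistic = "trial proportion",
                         sem_fun = function(v) sd(v) / sqrt(length(v)))
}

#' Proportion of participants who ever chose a rule set
#'
#' A binary per-participant indicator of having chosen a rule from
#' `rule_set` at least once in the condition, summarised as the proportion
#' of participants +/- the binomial standard error `sqrt(p(1-p)/n)`.
#'
#' @inheritParams choice_proportion_summary
#' @return A `proportion_summary`.
#' @export
ever_chose_summary <- function(decisions, condition, rule_set) {
  per <- participant_values(
    decisions, condition,
    function(rules) as.numeric(any(rules %in% rule_set)))
  new_proportion_summary(per, condition, rule_set,
                         statistic = "ever-chose proportion",
                         sem_fun = function(v) {
                           p <- mean(v)
                           sqrt(p * (1 - p) / length(v))
                         })
}

participant_values <- function(decisions, condition, fn) {
  condition <- match_levels(condition, condition_levels(), "condition")
  d <- dplyr::filter(decisions, !.data$is_lottery,
                     .data$condition == !!condition)
  all_ids <- unique(decisions$participant_id)
  dropped <- setdiff(all_ids, unique(d$participant_id))
  if (length(dropped) > 0) {
    warn(sprintf("dropping %d participant(s) with no qualifying trials: %s",
                 length(dropped), paste(dropped, collapse = ", ")))
  }
  if (nrow(d) == 0) abort("no qualifying trials in this condition")
  dplyr::summarise(dplyr::group_by(d, .data$participant_id),
                   value = fn(.data$chosen_rule), .groups = "drop")
}

new_proportion_summary <- function(per, condition, rule_set, statistic,
                                   sem_fun) {
  structure(list(per_participant = per,
                 condition = condition, rule_set = rule_set,
                 statistic = statistic,
                 mean = mean(per$value), sem = sem_fun(per$value),
                 n = nrow(per)),
            class = "proportion_summary")
}

#' @export
print.proportion_summary <- function(x, ...) {
  cat(sprintf("<proportion_summary> %s of {%s} in %s: %.1f%% +/- %.1f%% (n = %d)\n",
              x$statistic, paste(x$rule_set, collapse = ", "), x$condition,
              100 * x$mean, 100 * x$sem, x$n))
  invisible(x)
}

#' @rdname choice_proportion_summary
#' @param x A `proportion_summary`.
#' @param ... Unused.
#' @export
tidy.proportion_summary <- function(x, ...) x$per_participant

#' @rdname choice_proportion_summary
#' @export
glance.proportion_summary <- function(x, ...) {
  tibble::tibble(condition = x$condition,
                 rule_set = paste(x$rule_set, collapse = "+"),
                 statistic = x$statistic,
                 mean = x$mean, sem = x$sem, n = x$n)
}

#' Two-sample comparison of group means
#'
#' Two-tailed t test between two groups of values (Welch by default; set
#' `var_equal = TRUE` for the pooled-variance variant), as used to compare
#' thermometer ratings or trial outcomes between attitude groups.
#'
#' @param x,y Numeric vectors (each of length >= 2 with non-degenerate
#'   variance in at least one group).
#' @param var_equal Assume equal variances? Default `FALSE` (Welch).
#' @return One-row tibble: `estimate_x`, `estimate_y`, `statistic`, `df`,
#'   `p_value`, `method`.
#' @export
group_mean_test <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs at least two observations")
  }
  ht <- t.test(x, y, var.equal = var_equal)
  tibble::tibble(estimate_x = mean(x), estimate_y = mean(y),
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value, method = ht$method)
}

#' Chi-squared test on a 2 x 2 contingency table
#'
#' Pearson chi-squared without continuity correction by default; set
#' `correct = TRUE` for the Yates-corrected variant.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @param correct Apply Yates continuity correction? Default `FALSE`.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @examples
#' chi2_2x2(matrix(c(6, 2, 13, 29), nrow = 2))
#' @export
chi2_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)))
  if (any(table < 0) || any(table != round(table))) {
    abort("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero marginal total", class = "voigame_zero_marginal_error")
  }
  ht <- suppressWarnings(chisq.test(table, correct = correct))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value, method = ht$method)
}

#' Pearson correlation with two-tailed p value
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be
#'   constant.
#' @return One-row tibble: `estimate` (r), `statistic` (t), `df`,
#'   `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) abort("need at least three pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for constant input",
          class = "voigame_constant_input_error")
  }
  ht <- cor.test(x, y, method = "pearson")
  tibble::tibble(estimate = unname(ht$estimate),
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value, n = length(x))
}

#' Participant-level cluster bootstrap
#'
#' Resamples whole participants (all of their rows) with replacement and
#' recomputes a statistic on each replicate, respecting the
#' non-independence of rows belonging to the same participant. The
#' percentile confidence interval and whether it excludes `null_value` are
#' reported; deterministic given `seed`.
#'
#' @param data Tibble with a cluster id column.
#' @param statistic_fn Function taking a data subset (same columns as
#'   `data`) and returning a single number. A replicate on which
#'   `statistic_fn` errors is recorded and redrawn, up to `max_failures`
#'   failures in total.
#' @param cluster Name of the cluster id column. Default
#'   `"participant_id"`.
#' @param B Number of bootstrap replicates (>= 100). Default 2000.
#' @param conf Confidence level. Default 0.95.
#' @param seed Optional integer seed (applied locally; the global RNG state
#'   is untouched).
#' @param null_value Null value for the exclusion flag. Default 0.
#' @param max_failures Cap on total failed replicates. Default 100.
#' @return A `bootstrap_result`: list with `estimate`, `replicates`,
#'   `ci_lower`, `ci_upper`, `conf`, `null_value`, `excludes_null`, `B`,
#'   `n_clusters`, `n_failures`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 6, seed = 5))
#' cluster_bootstrap(cohort$neural, function(d) mean(d$outcome),
#'                   B = 200, seed = 1)
#' @export
cluster_bootstrap <- function(data, statistic_fn, cluster = "participant_id",
                              B = 2000, conf = 0.95, seed = NULL,
                              null_value = 0, max_failures = 100) {
  stopifnot(cluster %in% names(data), B >= 100, conf > 0, conf < 1)
  idx <- split(seq_len(nrow(data)), data[[cluster]])
  estimate <- statistic_fn(data)
  stopifnot(is.numeric(estimate), length(estimate) == 1)
  run <- function() {
    reps <- numeric(B)
    failures <- 0L
    for (b in seq_len(B)) {
      repeat {
        rows <- unlist(idx[sample.int(length(idx), replace = TRUE)],
                       use.names = FALSE)
        val <- tryCatch(statistic_fn(data[rows, , drop = FALSE]),
                        error = function(e) e)
        if (!inherits(val, "error")) break
        failures <- failures + 1L
        if (failures > max_failures) {
          abort(sprintf("statistic failed on more than %d replicates (last: %s)",
                        max_failures, conditionMessage(val)))
        }
      }
      reps[[b]] <- val
    }
    list(reps = reps, failures = failures)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  alpha <- 1 - conf
  ci <- unname(quantile(out$reps, c(alpha / 2, 1 - alpha / 2)))
  structure(list(estimate = estimate, replicates = out$reps,
                 ci_lower = ci[[1]], ci_upper = ci[[2]], conf = conf,
                 null_value = null_value,
                 excludes_null = null_value < ci[[1]] || null_value > ci[[2]],
                 B = B, n_clusters = length(idx),
                 n_failures = out$failures),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> estimate %.4f, %d%% percentile CI [%.4f, %.4f]\n",
              x$estimate, round(100 * x$conf), x$ci_lower, x$ci_upper))
  cat(sprintf("  B = %d over %d clusters; CI %s the null value %g\n",
              x$B, x$n_clusters,
              if (x$excludes_null) "excludes" else "covers", x$null_value))
  invisible(x)
}

#' @rdname cluster_bootstrap
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @export
tidy.bootstrap_result <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, ci_lower = x$ci_lower,
                 ci_upper = x$ci_upper, conf = x$conf,
                 excludes_null = x$excludes_null)
}

#' @rdname cluster_bootstrap
#' @export
glance.bootstrap_result <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, ci_lower = x$ci_lower,
                 ci_upper = x$ci_upper, conf = x$conf, B = x$B,
                 n_clusters = x$n_clusters, n_failures = x$n_failures,
                 excludes_null = x$excludes_null)
}
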