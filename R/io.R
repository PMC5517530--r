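# Table schemas: required columns, with an optional enum constraint or a
# predicate checked cell-wise.
table_schemas <- function() {
  list(
    decisions = list(
      participant_id = "character", session_id = "character",
      session_type = c("voting", "dictatorship"),
      info_type = c("voi", "informed"),
      round_index = "numeric",
      condition = condition_levels(),
      assigned_class = c(class_levels(), NA),
      chosen_rule = rule_levels(), society_rule = rule_levels(),
      decider = c("vote", "self_dictator", "partner_dictator"),
      payoff = "numeric",
      partner1_class = c(class_levels(), NA),
      partner2_class = c(class_levels(), NA),
      partner1_payoff = "numeric", partner2_payoff = "numeric",
      is_lottery = "logical"),
    affect = list(
      participant_id = "character", session_id = "character",
      partner_id = c("partner1", "partner2"),
      latent_attitude = c("accordance", "non_accordance", NA),
      rating_I = "rating", rating_II = "rating", rating_III = "rating"),
    incomes = list(
      participant_id = "character", session_id = "character",
      player = c("self", "partner1", "partner2"),
      total_income = "numeric"),
    neural = list(
      participant_id = "character", session_id = "character",
      round_index = "numeric",
      condition = condition_levels(), chosen_rule = rule_levels(),
      outcome = "numeric"))
}

validate_table <- function(df, schema, file) {
  missing <- setdiff(names(schema), names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing column(s) %s", file,
                  paste(missing, collapse = ", ")),
          class = "voigame_schema_error")
  }
  for (col in names(schema)) {
    spec <- schema[[col]]
    x <- df[[col]]
    bad <- if (identical(spec, "numeric")) {
      !is.na(x) & !is.finite(suppressWarnings(as.numeric(x)))
    } else if (identical(spec, "rating")) {
      xn <- suppressWarnings(as.numeric(x))
      is.na(xn) | xn < 0 | xn > 100
    } else if (identical(spec, "logical")) {
      is.na(as.logical(x))
    } else if (identical(spec, "character")) {
      is.na(x) | x == ""
    } else {
      allow_na <- anyNA(spec)
      !(x %in% spec) & !(allow_na & is.na(x))
    }
    if (any(bad)) {
      row <- which(bad)[[1]]
      abort(sprintf("%s: invalid value '%s' in column '%s', row %d",
                    file, as.character(df[[col]][[row]]), col, row),
            class = "voigame_schema_error")
    }
  }
  invisible(df)
}

#' Read and validate the four cohort tables
#'
#' Reads `decisions.csv`, `affect.csv`, `incomes.csv` and `neural.csv` from
#' a directory (comment lines starting with `#` are ignored), validates
#' every categorical field against its documented coding, and checks
#' referential integrity: every participant referenced in the affect,
#' income and neural tables must appear in the decisions table.
#'
#' @param dir Directory containing the four CSV files.
#' @return A list of validated tibbles `decisions`, `affect`, `incomes`,
#'   `neural`.
#' @export
read_cohort_tables <- function(dir) {
  schemas <- table_schemas()
  tables <- lapply(names(schemas), function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      abort(sprintf("missing table file: %s", path),
            class = "voigame_schema_error")
    }
    df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
    validate_table(df, schemas[[nm]], basename(path))
  })
  names(tables) <- names(schemas)
  known <- unique(tables$decisions$participant_id)
  for (nm in c("affect", "incomes", "neural")) {
    stray <- setdiff(unique(tables[[nm]]$participant_id), known)
    if (length(stray) > 0) {
      abort(sprintf("%s.csv references unknown participant(s): %s",
                    nm, paste(stray, collapse = ", ")),
            class = "voigame_integrity_error")
    }
  }
  tables
}

write_stamped_csv <- function(df, path, hash) {
  lines <- c(sprintf("# config_hash: %s", hash),
             sub("\n$", "", readr::format_csv(df)))
  writeLines(lines, path)
  invisible(path)
}

#' Write the cohort tables to a directory
#'
#' @param cohort A `voi_cohort` (or a list with the four tables).
#' @param dir Output directory (created if needed).
#' @param hash Config hash stamped as a comment line into each file.
#' @return `dir`, invisibly.
#' @export
write_cohort_tables <- function(cohort, dir, hash = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("decisions", "affect", "incomes", "neural")) {
    write_stamped_csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")), hash)
  }
  invisible(dir)
}

#' Read and validate a run configuration
#'
#' The run configuration is a YAML file with blocks `scheme`, `cohort`,
#' `policy`, `affect`, `neural`, `analysis` plus top-level `seed` and
#' `out_dir`. Unknown keys anywhere are rejected. A reference configuration
#' with all defaults ships with the package:
#' `system.file("extdata", "default-config.yaml", package = "voigame")`.
#'
#' @param path Path to a YAML file, or a named list with the same
#'   structure.
#' @return A validated `voigame_run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  template <- list(
    scheme = list(h = NULL, m = NULL, l = NULL, cost_rate = NULL,
                  intermediate_fraction = NULL),
    cohort = list(n_participants = NULL, rounds_per_session = NULL,
                  n_lottery = NULL, dictator_fraction = NULL),
    policy = "block", affect = "block", neural = "block",
    analysis = list(bootstrap_B = NULL, conf = NULL,
                    target_condition = NULL, target_rule = NULL,
                    baseline_condition = NULL, baseline_rule = NULL,
                    by_participant = NULL),
    seed = NULL, out_dir = NULL)
  check_keys(raw, template, "config")
  cfg_args <- list()
  for (blk in c("cohort", "policy", "affect", "neural")) {
    if (blk == "cohort") {
      cfg_args <- c(cfg_args, raw$cohort %||% list())
    } else {
      cfg_args[[blk]] <- raw[[blk]] %||% list()
    }
  }
  if (!is.null(raw$scheme)) {
    cfg_args$scheme <- do.call(payoff_scheme, raw$scheme)
  }
  if (!is.null(raw$seed)) cfg_args$seed <- raw$seed
  cohort_cfg <- do.call(cohort_config, cfg_args)

  analysis_def <- list(bootstrap_B = 2000, conf = 0.95,
                       target_condition = "voi", target_rule = "equality",
                       baseline_condition = "high",
                       baseline_rule = "inequality",
                       by_participant = FALSE)
  analysis <- merge_params(analysis_def, raw$analysis %||% list(), "analysis")
  structure(list(cohort = cohort_cfg, analysis = analysis,
                 out_dir = raw$out_dir),
            class = "voigame_run_config")
}

check_keys <- function(raw, template, where) {
  unknown <- setdiff(names(raw), names(template))
  if (length(unknown) > 0) {
    abort(sprintf("unknown key(s) in %s: %s", where,
                  paste(unknown, collapse = ", ")),
          class = "voigame_config_error")
  }
  for (nm in names(raw)) {
    if (is.list(template[[nm]]) && is.list(raw[[nm]])) {
      check_keys(raw[[nm]], template[[nm]], paste0(where, "$", nm))
    }
  }
  # "block" entries (policy/affect/neural) are validated by cohort_config()
  invisible(raw)
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort (or ingests one from `in_dir`), computes the affect
#' screen, the behavioural choice summaries, the interaction decomposition
#' on the trial-level neural outcomes, and participant-level cluster
#' bootstraps of the headline quantities. All stage outputs are written to
#' `out_dir` as CSVs stamped with the configuration hash, together with a
#' plain-text log recording the seed and every exclusion decision.
#'
#' @param config A `voigame_run_config` from [read_run_config()], or a
#'   [cohort_config()] (analysis defaults then apply).
#' @param out_dir Output directory; overrides the config's `out_dir`. With
#'   `NULL` and no configured directory, nothing is written.
#' @param in_dir Optional directory of existing cohort tables to analyse
#'   instead of simulating.
#' @return A `voigame_report` list: `cohort`, `screen`, `behavior`,
#'   `correlation`, `decomposition`, `bootstrap_pi`,
#'   `bootstrap_correlation`, `config_hash`.
#' @examples
#' cfg <- read_run_config(list(cohort = list(n_participants = 6),
#'                             analysis = list(bootstrap_B = 100)))
#' rep <- run_pipeline(cfg)
#' rep$behavior
#' @export
run_pipeline <- function(config, out_dir = NULL, in_dir = NULL) {
  if (inherits(config, "cohort_config")) {
    config <- structure(
      list(cohort = config,
           analysis = read_run_config(list())$analysis, out_dir = NULL),
      class = "voigame_run_config")
  }
  stopifnot(inherits(config, "voigame_run_config"))
  out_dir <- out_dir %||% config$out_dir
  hash <- rlang::hash(config)
  log_lines <- c(sprintf("voigame %s", as.character(utils::packageVersion("voigame"))),
                 sprintf("config_hash %s", hash),
                 sprintf("seed %d", config$cohort$seed))

  cohort <- if (is.null(in_dir)) {
    generate_cohort(config$cohort)
  } else {
    tabs <- read_cohort_tables(in_dir)
    structure(c(tabs, list(config = config$cohort)), class = "voi_cohort")
  }

  # affect screen
  cases <- attitude_cases(cohort$affect, cohort$incomes)
  screen <- apply_exclusions(cases)
  log_lines <- c(log_lines, sprintf(
    "exclude %s %s %s reason=%s",
    screen$excluded$participant_id, screen$excluded$session_id,
    screen$excluded$partner_id, screen$excluded$reason))

  # behavioural summaries
  behavior <- dplyr::bind_rows(lapply(c("voi", "high", "low"), function(cc) {
    dplyr::bind_rows(
      glance(choice_proportion_summary(cohort$decisions, cc, selfless_rules(cc))),
      glance(choice_proportion_summary(cohort$decisions, cc, selfish_rules(cc))),
      glance(ever_chose_summary(cohort$decisions, cc, selfless_rules(cc))),
      glance(ever_chose_summary(cohort$decisions, cc, selfish_rules(cc))))
  }))

  # relative income vs affective change after disclosure, across all cases
  rel <- session_relative_income(cohort$incomes)
  case_rel <- dplyr::left_join(cases, rel,
                               by = c("participant_id", "session_id"))
  correlation <- pearson_r(case_rel$relative_income,
                           case_rel$delta_disclosure)

  # interaction decomposition on trial-level neural outcomes
  an <- config$analysis
  cells <- cell_means(
    cohort$neural,
    participant = if (isTRUE(an$by_participant)) "participant_id" else NULL)
  target <- c(an$target_condition, an$target_rule)
  baseline <- c(an$baseline_condition, an$baseline_rule)
  decomposition <- tryCatch(
    decompose_interaction(cells, target, baseline),
    voigame_empty_cell_error = function(e) {
      abort(paste0(conditionMessage(e),
                   " — increase rounds_per_session or choose a contrast",
                   " over populated cells"),
            class = "voigame_empty_cell_error")
    })

  boot_pi <- cluster_bootstrap(
    cohort$neural,
    function(d) decompose_interaction(cell_means(d), target, baseline)$pi,
    B = an$bootstrap_B, conf = an$conf, seed = config$cohort$seed)
  boot_r <- cluster_bootstrap(
    case_rel,
    function(d) pearson_r(d$relative_income, d$delta_disclosure)$estimate,
    B = an$bootstrap_B, conf = an$conf, seed = config$cohort$seed + 1L)

  report <- structure(
    list(cohort = cohort, screen = screen, behavior = behavior,
         correlation = correlation, decomposition = decomposition,
         bootstrap_pi = boot_pi, bootstrap_correlation = boot_r,
         config_hash = hash),
    class = "voigame_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_tables(cohort, out_dir, hash)
    write_stamped_csv(dplyr::mutate(screen$retained, retained = TRUE),
                      file.path(out_dir, "attitudes.csv"), hash)
    write_stamped_csv(screen$accounting,
                      file.path(out_dir, "exclusion_accounting.csv"), hash)
    write_stamped_csv(behavior, file.path(out_dir, "behavior.csv"), hash)
    write_stamped_csv(
      dplyr::bind_cols(glance(decomposition),
                       tibble::tibble(pi_ci_lower = boot_pi$ci_lower,
                                      pi_ci_upper = boot_pi$ci_upper)),
      file.path(out_dir, "decomposition.csv"), hash)
    write_stamped_csv(correlation, file.path(out_dir, "correlation.csv"), hash)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  report
}

#' @export
print.voigame_report <- function(x, ...) {
  cat("<voigame_report>\n")
  print(x$screen)
  voi_self <- x$behavior[x$behavior$condition == "voi" &
                           x$behavior$rule_set == "equality" &
                           x$behavior$statistic == "trial proportion", ]
  cat(sprintf("  VoI equality share: %.1f%% +/- %.1f%%\n",
              100 * voi_self$mean, 100 * voi_self$sem))
  cat(sprintf("  relative income vs disclosure change: r = %.3f (p = %.3g)\n",
              x$correlation$estimate, x$correlation$p_value))
  print(x$decomposition)
  cat(sprintf("  bootstrap pi CI [%.4f, %.4f]\n",
              x$bootstrap_pi$ci_lower, x$bootstrap_pi$ci_upper))
  invisible(x)
}
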