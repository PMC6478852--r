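round_numeric <- function(df, digits = 4) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                  ~ round(.x, digits)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate (or ingest) -> behavioural metrics -> model fitting
#' -> model comparison -> statistics -> report. The report bundle mirrors
#' the study's Results layout: a per-phase choice summary, figure-style
#' summary CSVs (mean accuracy per phase; mean choice percentage per
#' symbol), a two-way ANOVA grid (time x drug for accuracy and each
#' choice), a paired t-test / Bayes-factor grid for the 24-hour phase, a
#' Frank-style medication x choice (choose-A vs avoid-F) ANOVA,
#' dose-response regressions, per-unit fit tables and — when two or more
#' models are fitted — a mean-BIC model comparison, plus a run log
#' recording the master seed. Report tables are written with 4 decimals.
#'
#' No multiplicity correction is applied across the report's tests,
#' matching the uncorrected per-test reporting convention the tables
#' emulate; a footnote in the report says so.
#'
#' @param out_dir Output directory for the report bundle.
#' @param cohort A `gl_cohort`, a directory path to [read_cohort()] from,
#'   or `NULL` to generate a synthetic cohort.
#' @param cohort_cfg [cohort_config()] used when `cohort` is `NULL`;
#'   defaults to the standard 31-subject null-effect cohort seeded from
#'   `seed`.
#' @param models Models to fit (subset of [gl_models()]).
#' @param n_starts Optimisation starts per fit.
#' @param bf_prior_scale Cauchy prior width for all Bayes factors.
#' @param include_early_phases Include choice0/choice30 in the likelihood.
#' @param threshold_rule Optional learner-selection rule
#'   (see [threshold_learners()]); retained units are written to
#'   `learners.csv`.
#' @param seed Master seed; every stage derives a named substream.
#' @param verbose Log progress to stderr?
#' @return Invisibly, a `gl_report` list with all computed objects and file
#'   paths.
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(tempfile("glrun"),
#'                     cohort_cfg = cohort_config(n_subjects = 4, seed = 7),
#'                     models = "qlearning", n_starts = 2, seed = 7,
#'                     verbose = FALSE)
#' rep$comparison
#' }
run_pipeline <- function(out_dir, cohort = NULL, cohort_cfg = NULL,
                         models = "qlearning", n_starts = 10,
                         bf_prior_scale = 0.707,
                         include_early_phases = FALSE,
                         threshold_rule = NULL, seed = 1, verbose = TRUE) {
  models <- unique(models)
  stopifnot(all(models %in% gl_models()))  # empty = statistics only
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      say("stage '%s' FAILED: %s", name, conditionMessage(e))
      writeLines(log_lines, log_path)
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  say("pipeline start | master seed %d | models: %s", seed,
      paste(models, collapse = ", "))

  cohort <- stage("input", {
    if (is.null(cohort)) {
      cfg <- cohort_cfg %||% cohort_config(seed = substream_seed(seed, "cohort"))
      say("generating synthetic cohort: %d subjects, model %s",
          cfg$n_subjects, cfg$model)
      generate_cohort(cfg)
    } else if (is.character(cohort)) {
      say("reading cohort from %s", cohort)
      read_cohort(cohort)
    } else {
      stopifnot(inherits(cohort, "gl_cohort"))
      cohort
    }
  })

  summary_tbl <- stage("metrics", choice_summary(cohort$trials))
  readr::write_csv(round_numeric(summary_tbl),
                   file.path(out_dir, "choice_summary.csv"))

  fig4 <- summary_tbl |>
    dplyr::group_by(.data$condition, .data$phase) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     sd_accuracy = sd(.data$accuracy), .groups = "drop")
  readr::write_csv(round_numeric(fig4), file.path(out_dir, "fig4_accuracy.csv"))

  fig5 <- summary_tbl |>
    tidyr::pivot_longer(dplyr::starts_with("choose_"),
                        names_to = "symbol", names_prefix = "choose_",
                        values_to = "choose") |>
    dplyr::group_by(.data$condition, .data$phase, .data$symbol) |>
    dplyr::summarise(mean_choose = mean(.data$choose),
                     sd_choose = sd(.data$choose), .groups = "drop")
  readr::write_csv(round_numeric(fig5), file.path(out_dir, "fig5_choices.csv"))

  measures <- c("accuracy", paste0("choose_", LETTERS[1:6]))
  anova_grid <- stage("anova", {
    purrr::map_dfr(measures, function(m) {
      a <- rm_anova(summary_tbl, m, "subject", c("phase", "condition"))
      dplyr::bind_cols(tibble::tibble(measure = m), tidy(a))
    })
  })
  readr::write_csv(round_numeric(anova_grid),
                   file.path(out_dir, "anova_table.csv"))

  ttests <- stage("ttests", {
    wide24 <- summary_tbl |>
      dplyr::filter(.data$phase == "choice24h") |>
      tidyr::pivot_wider(id_cols = "subject", names_from = "condition",
                         values_from = dplyr::all_of(measures))
    purrr::map_dfr(measures, function(m) {
      tt <- paired_ttest(wide24[[paste0(m, "_drug")]],
                         wide24[[paste0(m, "_placebo")]],
                         prior_scale = bf_prior_scale)
      dplyr::bind_cols(tibble::tibble(measure = m), tidy(tt))
    })
  })
  readr::write_csv(round_numeric(ttests), file.path(out_dir, "ttest_table.csv"))

  # Frank-style 2x2: medication x (choose-A vs avoid-F) on the 24-h phase
  frank <- stage("frank_anova", {
    long <- summary_tbl |>
      dplyr::filter(.data$phase == "choice24h") |>
      tidyr::pivot_longer(c("choose_A", "avoid_F"), names_to = "choice",
                          values_to = "pct")
    rm_anova(long, "pct", "subject", c("condition", "choice"))
  })
  readr::write_csv(round_numeric(tidy(frank)),
                   file.path(out_dir, "choiceA_avoidF_anova.csv"))

  doses <- NULL
  if (!is.null(cohort$meta)) {
    doses <- stage("dose_response", {
      meta <- weight_adjusted_dose(cohort$meta)
      wide24 <- summary_tbl |>
        dplyr::filter(.data$phase == "choice24h") |>
        tidyr::pivot_wider(id_cols = "subject", names_from = "condition",
                           values_from = "accuracy") |>
        dplyr::left_join(meta, by = "subject")
      diff <- wide24$drug - wide24$placebo
      degrees <- c(1, 2)[c(1, 2) + 1 < sum(complete.cases(diff))]
      purrr::map_dfr(degrees,
                     ~ dose_response(wide24$dose_per_kg, diff, .x))
    })
    readr::write_csv(round_numeric(doses),
                     file.path(out_dir, "dose_response.csv"))
  }

  learners <- NULL
  if (!is.null(threshold_rule)) {
    learners <- stage("threshold", threshold_learners(cohort$trials,
                                                      threshold_rule))
    readr::write_csv(learners, file.path(out_dir, "learners.csv"))
    say("threshold rule '%s': %d subject-conditions retained",
        threshold_rule, nrow(learners))
  }

  fits <- if (length(models) == 0) NULL else stage("fit", {
    purrr::map_dfr(models, function(m) {
      say("fitting %s (%d starts per unit)", m, n_starts)
      fit_cohort(cohort$trials, m, n_starts = n_starts,
                 seed = substream_seed(seed, paste("fit", m)),
                 include_early_phases = include_early_phases)
    })
  })
  if (!is.null(fits)) {
    readr::write_csv(round_numeric(fits), file.path(out_dir, "fits.csv"))
  }

  comparison <- NULL
  if (length(models) >= 2) {
    comparison <- stage("compare", compare_models(fits))
    readr::write_csv(round_numeric(comparison$summary),
                     file.path(out_dir, "model_comparison.csv"))
    say("model comparison winner: %s",
        if (comparison$tie) "tie" else comparison$winner)
  }

  param_tests <- if (length(models) == 0) NULL else stage("param_tests", {
    m1 <- models[1]
    pars <- names(param_layout(m1))
    wide <- fits |>
      dplyr::filter(.data$model == m1) |>
      tidyr::pivot_wider(id_cols = "subject", names_from = "condition",
                         values_from = dplyr::all_of(pars))
    purrr::map_dfr(pars, function(p) {
      tt <- paired_ttest(wide[[paste0(p, "_drug")]],
                         wide[[paste0(p, "_placebo")]],
                         prior_scale = bf_prior_scale)
      dplyr::bind_cols(tibble::tibble(model = m1, parameter = p), tidy(tt))
    })
  })
  if (!is.null(param_tests)) {
    readr::write_csv(round_numeric(param_tests),
                     file.path(out_dir, "parameter_tests.csv"))
  }

  stage("report", {
    lines <- c(
      "# GainLoss pipeline report", "",
      sprintf("Master seed: %d. Models fitted: %s.", seed,
              paste(models, collapse = ", ")),
      sprintf("Cohort: %d subjects x 2 conditions (%d trials).",
              length(unique(cohort$trials$subject)), nrow(cohort$trials)),
      "",
      "## 24-hour paired tests (drug vs placebo)", "",
      knit_md_table(round_numeric(ttests)),
      "",
      "## Time x drug ANOVAs", "",
      knit_md_table(round_numeric(
        anova_grid[, c("measure", "effect", "df1_reported", "df2_reported",
                       "F", "p_reported", "pes")])),
      if (!is.null(param_tests)) c(
        "", "## Model parameter tests", "",
        knit_md_table(round_numeric(param_tests))),
      if (!is.null(comparison)) c(
        "", "## Model comparison (mean BIC)", "",
        knit_md_table(round_numeric(comparison$summary))),
      "",
      paste("Note: p-values are reported per test without multiplicity",
            "correction, matching the table conventions this report",
            "emulates."))
    writeLines(unlist(lines), file.path(out_dir, "report.md"))
  })

  say("pipeline complete; outputs in %s", out_dir)
  writeLines(log_lines, log_path)
  res <- list(cohort = cohort, choice_summary = summary_tbl,
              anova_grid = anova_grid, ttests = ttests, frank = frank,
              dose_response = doses, learners = learners, fits = fits,
              comparison = comparison, param_tests = param_tests,
              seed = seed, out_dir = out_dir)
  class(res) <- "gl_report"
  invisible(res)
}

# minimal markdown table writer for the report
knit_md_table <- function(df) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::everything(), as.character))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

#' @export
print.gl_report <- function(x, ...) {
  cat(sprintf("<gl_report: seed %d, outputs in %s>\n", x$seed, x$out_dir))
  invisible(x)
}
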