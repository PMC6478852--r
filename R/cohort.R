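#' Population hyperparameters for simulated agents
#'
#' Population distributions are normal on the fitting scale — logit for
#' learning rates, log for inverse temperatures / gains — so parameters stay
#' in bounds without truncation. The defaults are calibrated to the study's
#' qualitative behavioural pattern: near-chance learning-phase accuracy
#' (~55%) with clearly above-chance 24-hour transfer accuracy (~65-75%),
#' driven by a low day-1 inverse temperature and a higher day-2 one.
#'
#' @param model `"qlearning"` or `"opal"`.
#' @return A list with named numeric vectors `mean` and `sd` on the
#'   transformed scale.
#' @export
#' @examples
#' param_population("qlearning")
param_population <- function(model = c("qlearning", "opal")) {
  model <- arg_match(model)
  if (model == "qlearning") {
    list(mean = c(alpha_pos = qlogis(0.25), alpha_neg = qlogis(0.18),
                  beta = log(0.7), beta_day2 = log(1.8)),
         sd = c(alpha_pos = 0.7, alpha_neg = 0.7, beta = 0.4,
                beta_day2 = 0.4))
  } else {
    list(mean = c(alpha_g = qlogis(0.3), alpha_n = qlogis(0.3),
                  beta_g = log(1.5), beta_n = log(0.7),
                  beta_g_day2 = log(3), beta_n_day2 = log(1.5)),
         sd = c(alpha_g = 0.7, alpha_n = 0.7, beta_g = 0.4, beta_n = 0.4,
                beta_g_day2 = 0.4, beta_n_day2 = 0.4))
  }
}

# draw n parameter sets on the natural scale from a population definition
draw_params <- function(model, population, n) {
  layout <- param_layout(model)
  if (!setequal(names(population$mean), names(layout)) ||
      any(population$sd < 0)) {
    abort("Population hyperparameters must name every model parameter and have sd >= 0.")
  }
  z <- vapply(names(layout), function(p) {
    rnorm(n, population$mean[[p]], population$sd[[p]])
  }, numeric(n))
  z <- matrix(z, nrow = n, dimnames = list(NULL, names(layout)))
  nat <- z
  for (p in names(layout)) {
    nat[, p] <- if (layout[[p]] == "alpha") plogis(z[, p]) else exp(z[, p])
  }
  out <- tibble::as_tibble(nat)
  attr(out, "transformed") <- z
  out
}

#' Configuration for a synthetic crossover cohort
#'
#' Describes a within-subject drug/placebo study: every subject completes
#' both conditions (practice, two 90-trial learning blocks, and three
#' 90-trial feedback-free choice phases per condition), with agent
#' parameters drawn once per subject and a configurable additive drug
#' effect on the transformed day-2 choice parameter(s). A zero drug effect
#' gives a null cohort in which drug and placebo parameters are identical
#' within subject.
#'
#' @param n_subjects Number of subjects completing both conditions
#'   (`>= 2`; 31 by default).
#' @param model Generating model, `"qlearning"` or `"opal"`.
#' @param population Population hyperparameters ([param_population()]).
#' @param drug_effect Named numeric: additive shifts applied on the
#'   transformed (log) scale to day-2 choice parameters in the drug
#'   condition, e.g. `c(beta_day2 = 0.5)`; default no effect.
#' @param missingness Probability that any one choice phase of a
#'   subject-condition is absent from the observed data (`[0, 1)`).
#' @param weight_mean,weight_sd Body-weight distribution (kg).
#' @param age_mean,age_sd Age distribution (years), truncated at 65.
#' @param moca_mean,moca_sd MoCA distribution, capped at 30.
#' @param dose_mg Levodopa dose (mg) given before the 24-hour phase.
#' @param seed Master seed; all randomness descends from it via named
#'   substreams.
#' @return A `gl_cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 31, model = c("qlearning", "opal"),
                          population = param_population(model),
                          drug_effect = NULL, missingness = 0,
                          weight_mean = 75, weight_sd = 12,
                          age_mean = 71.2, age_sd = 7.4,
                          moca_mean = 26.2, moca_sd = 3.1,
                          dose_mg = 150, seed = 1) {
  model <- arg_match(model)
  assert_scalar_number(n_subjects, "n_subjects", lower = 2)
  assert_scalar_number(missingness, "missingness", 0, 1 - 1e-9)
  drug_effect <- drug_effect %||% setNames(numeric(0), character(0))
  day2 <- grep("day2", names(param_layout(model)), value = TRUE)
  if (length(drug_effect) && !all(names(drug_effect) %in% day2)) {
    abort(sprintf("`drug_effect` may only shift day-2 parameters (%s).",
                  paste(day2, collapse = ", ")))
  }
  structure(list(n_subjects = as.integer(n_subjects), model = model,
                 population = population, drug_effect = drug_effect,
                 missingness = missingness, weight_mean = weight_mean,
                 weight_sd = weight_sd, age_mean = age_mean, age_sd = age_sd,
                 moca_mean = moca_mean, moca_sd = moca_sd, dose_mg = dose_mg,
                 seed = as.integer(seed)),
            class = "gl_cohort_config")
}

#' Draw per-subject drug and placebo parameters
#'
#' Placebo parameters are drawn from the population distributions; drug
#' parameters equal the same subject's placebo parameters with the
#' configured day-2 shift applied on the transformed scale, preserving the
#' within-subject coupling of a crossover design.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per subject x condition, columns `subject`,
#'   `condition` and the model's parameters on the natural scale.
#' @export
draw_subject_params <- function(config) {
  stopifnot(inherits(config, "gl_cohort_config"))
  layout <- param_layout(config$model)
  with_seed(substream_seed(config$seed, "params"), {
    placebo <- draw_params(config$model, config$population, config$n_subjects)
    z <- attr(placebo, "transformed")
    z_drug <- z
    for (p in names(config$drug_effect)) {
      z_drug[, p] <- z_drug[, p] + config$drug_effect[[p]]
    }
    drug <- z_drug
    for (p in names(layout)) {
      drug[, p] <- if (layout[[p]] == "alpha") plogis(z_drug[, p]) else exp(z_drug[, p])
    }
    dplyr::bind_rows(
      dplyr::bind_cols(tibble::tibble(subject = seq_len(config$n_subjects),
                                      condition = "placebo"), placebo),
      dplyr::bind_cols(tibble::tibble(subject = seq_len(config$n_subjects),
                                      condition = "drug"),
                       tibble::as_tibble(drug))
    ) |> dplyr::arrange(.data$subject, .data$condition)
  })
}

#' Generate a complete synthetic cohort
#'
#' Simulates every subject through both conditions with the standard
#' session structure, draws subject metadata (condition order
#' counterbalanced, body weight, age, MoCA), and optionally removes whole
#' choice phases at the configured missingness rate (absent, never
#' zero-filled). Ground-truth generating parameters are retained separately
#' from the observed tables, for recovery testing only.
#'
#' @param config A [cohort_config()].
#' @return A `gl_cohort`: `trials` (observed trial tibble), `meta` (subject
#'   metadata), `truth` (generating parameters) and `config`. Reproducible
#'   bit-for-bit from `config$seed`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 2, seed = 42))
#' dplyr::count(coh$trials, phase)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "gl_cohort_config"))
  truth <- draw_subject_params(config)
  n <- config$n_subjects

  meta <- with_seed(substream_seed(config$seed, "meta"), {
    weight <- pmax(rnorm(n, config$weight_mean, config$weight_sd), 40)
    age <- pmax(rnorm(n, config$age_mean, config$age_sd), 65)
    moca <- pmin(round(rnorm(n, config$moca_mean, config$moca_sd)), 30)
    tibble::tibble(
      subject = seq_len(n),
      order = ifelse(seq_len(n) %% 2 == 1, "drug_first", "placebo_first"),
      weight_kg = weight, age = age, moca = moca,
      dose_mg = config$dose_mg)
  })

  layout_names <- names(param_layout(config$model))
  sims <- vector("list", 2 * n)
  for (s in seq_len(n)) {
    for (cond in c("drug", "placebo")) {
      row <- truth[truth$subject == s & truth$condition == cond, ]
      pars <- params_from_vector(config$model, unlist(row[layout_names]))
      sim <- with_seed(substream_seed(config$seed, paste("sim", s, cond)), {
        simulate_agent(pars, symbols = gl_symbols(cond))
      })
      attr(sim, "state") <- NULL
      sim$subject <- s
      sim$condition <- cond
      sims[[2 * (s - 1) + (cond == "placebo") + 1]] <- sim
    }
  }
  trials <- dplyr::bind_rows(sims)

  if (config$missingness > 0) {
    drop <- with_seed(substream_seed(config$seed, "missing"), {
      grid <- tidyr::expand_grid(subject = seq_len(n),
                                 condition = c("drug", "placebo"),
                                 phase = c("choice0", "choice30", "choice24h"))
      grid[runif(nrow(grid)) < config$missingness, ]
    })
    if (nrow(drop) > 0) {
      trials <- dplyr::anti_join(trials, drop,
                                 by = c("subject", "condition", "phase"))
    }
  }

  structure(list(trials = trials[, trial_cols], meta = meta, truth = truth,
                 config = config),
            class = "gl_cohort")
}

#' @export
print.gl_cohort <- function(x, ...) {
  cat(sprintf("<gl_cohort: %d subjects x 2 conditions, %d trials, model %s, seed %d>\n",
              x$config$n_subjects, nrow(x$trials), x$config$model,
              x$config$seed))
  invisible(x)
}

#' Write / read a cohort as plain-text files
#'
#' Observed data are written as tidy CSV (`trials.csv` with the schema
#' subject, condition, phase, block, trial_index, left_symbol, right_symbol,
#' chosen, outcome, reward, optimal; `meta.csv` with subject metadata);
#' ground truth goes to a separate `truth.csv` so observed and generating
#' information never mix. The round trip is lossless for the observed
#' tables.
#'
#' @param cohort A `gl_cohort`.
#' @param dir Directory to write into (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a `gl_cohort` (without the config, which is not serialised).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gl_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$trials, file.path(dir, "trials.csv"), na = "")
  readr::write_csv(cohort$meta, file.path(dir, "meta.csv"), na = "")
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"), na = "")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  tr_path <- file.path(dir, "trials.csv")
  if (!file.exists(tr_path)) abort(sprintf("No trials.csv under '%s'.", dir))
  trials <- readr::read_csv(
    tr_path, na = "",
    col_types = readr::cols(
      subject = readr::col_integer(), condition = readr::col_character(),
      phase = readr::col_character(), block = readr::col_integer(),
      trial_index = readr::col_integer(),
      left_symbol = readr::col_character(),
      right_symbol = readr::col_character(),
      chosen = readr::col_character(), outcome = readr::col_character(),
      reward = readr::col_double(), optimal = readr::col_logical()))
  bad <- which(!(trials$chosen %in% LETTERS[1:6]) |
                 !(trials$left_symbol %in% LETTERS[1:6]) |
                 !(trials$right_symbol %in% LETTERS[1:6]))
  if (length(bad)) {
    abort(sprintf("trials.csv: unknown symbol in row(s) %s.",
                  paste(head(bad, 5), collapse = ", ")))
  }
  bad_phase <- which(!trials$phase %in% task_phases)
  if (length(bad_phase)) {
    abort(sprintf("trials.csv: unknown phase in row(s) %s.",
                  paste(head(bad_phase, 5), collapse = ", ")))
  }
  meta <- NULL
  if (file.exists(file.path(dir, "meta.csv"))) {
    meta <- readr::read_csv(file.path(dir, "meta.csv"), na = "",
                            show_col_types = FALSE)
  }
  truth <- NULL
  if (file.exists(file.path(dir, "truth.csv"))) {
    truth <- readr::read_csv(file.path(dir, "truth.csv"), na = "",
                             show_col_types = FALSE)
  }
  structure(list(trials = trials, meta = meta, truth = truth, config = NULL),
            class = "gl_cohort")
}
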