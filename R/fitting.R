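#' Bayesian Information Criterion
#'
#' `BIC = 2 * NLL + k * log(n)` with `n` the number of modelled trials;
#' lower is better.
#'
#' @param nll Negative log-likelihood at the optimum.
#' @param k_params Number of free parameters.
#' @param n_trials Number of modelled trials (`>= 1`).
#' @return The BIC value.
#' @export
#' @examples
#' bic(100, 4, 270)
bic <- function(nll, k_params, n_trials) {
  if (!is.numeric(n_trials) || any(n_trials < 1)) {
    abort("`n_trials` must be >= 1.")
  }
  2 * nll + k_params * log(n_trials)
}

# free-parameter layout per model; alphas live on a logit scale and betas on
# a scaled-logit mapping to (0, 100), keeping fits bounded and identifiable
param_layout <- function(model) {
  switch(model,
    qlearning = c(alpha_pos = "alpha", alpha_neg = "alpha",
                  beta = "beta", beta_day2 = "beta"),
    opal = c(alpha_g = "alpha", alpha_n = "alpha", beta_g = "beta",
             beta_n = "beta", beta_g_day2 = "beta", beta_n_day2 = "beta"),
    abort(sprintf("Unknown model '%s'.", model))
  )
}

beta_max <- 100

transform_to_natural <- function(x, layout) {
  out <- ifelse(layout == "alpha", plogis(x), beta_max * plogis(x))
  setNames(out, names(layout))
}

transform_to_free <- function(est, layout) {
  p <- ifelse(layout == "alpha", est, est / beta_max)
  setNames(qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)), names(layout))
}

params_from_vector <- function(model, est) {
  if (model == "qlearning") {
    q_params(est[["alpha_pos"]], est[["alpha_neg"]], est[["beta"]],
             est[["beta_day2"]])
  } else {
    opal_params(est[["alpha_g"]], est[["alpha_n"]], est[["beta_g"]],
                est[["beta_n"]], est[["beta_g_day2"]], est[["beta_n_day2"]])
  }
}

#' Fit a model to one subject-condition by maximum likelihood
#'
#' Minimises [model_nll()] over bounded parameters via multi-start
#' Nelder-Mead on transformed coordinates (logit for learning rates,
#' scaled-logit onto `(0, 100)` for inverse temperatures / gains). The best
#' of `n_starts` random starting points is returned; given a seed the
#' result is fully reproducible.
#'
#' @param trials Trial tibble for a single subject-condition.
#' @param model `"qlearning"` or `"opal"`.
#' @param n_starts Number of random starts (`>= 1`; 10 by default).
#' @param seed Optional integer seed controlling the starting points.
#' @param include_early_phases Passed to [model_nll()].
#' @return A `gl_fit` object: estimates, `nll`, `n_trials`, `k`, `bic`,
#'   per-start NLLs, best-start index and a convergence flag. Methods:
#'   [tidy()], [glance()].
#' @export
#' @examples
#' set.seed(1)
#' sim <- simulate_agent(q_params())
#' fit <- fit_rl(sim, "qlearning", n_starts = 3, seed = 1)
#' glance(fit)
fit_rl <- function(trials, model = c("qlearning", "opal"), n_starts = 10,
                   seed = NULL, include_early_phases = FALSE) {
  model <- arg_match(model)
  assert_scalar_number(n_starts, "n_starts", lower = 1)
  if (nrow(trials) == 0) abort("Empty trial set: nothing to fit.")
  layout <- param_layout(model)
  # hoist the trial -> vector conversion out of the objective: the
  # optimiser evaluates the likelihood hundreds of times per start
  tr <- modelled_trials(trials, include_early_phases)
  n_tr <- nrow(tr)
  chosen <- match(tr$chosen, LETTERS[1:6]) - 1L
  other_sym <- ifelse(tr$chosen == tr$left_symbol, tr$right_symbol,
                      tr$left_symbol)
  other <- match(other_sym, LETTERS[1:6]) - 1L
  reward <- ifelse(is.na(tr$reward), 0, tr$reward)

  objective <- function(x) {
    est <- transform_to_natural(x, layout)
    if (model == "qlearning") {
      q_nll_cpp(chosen, other, reward, tr$update, tr$day2,
                est[["alpha_pos"]], est[["alpha_neg"]], est[["beta"]],
                est[["beta_day2"]])
    } else {
      opal_nll_cpp(chosen, other, reward, tr$update, tr$day2,
                   est[["alpha_g"]], est[["alpha_n"]],
                   (est[["alpha_g"]] + est[["alpha_n"]]) / 2,
                   est[["beta_g"]], est[["beta_n"]],
                   est[["beta_g_day2"]], est[["beta_n_day2"]])
    }
  }

  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      ifelse(layout == "alpha", runif(length(layout), -2, 2),
             runif(length(layout), -6, 0))
    })
  })

  runs <- lapply(starts, function(s) {
    tryCatch(
      optim(s, objective, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL
    )
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) abort("All optimisation starts failed.")
  nlls <- vapply(runs, function(r) if (is.null(r)) Inf else r$value, numeric(1))
  best <- which.min(nlls)
  est <- transform_to_natural(runs[[best]]$par, layout)
  params <- params_from_vector(model, est)
  structure(list(
    model = model,
    params = params,
    estimates = est,
    nll = runs[[best]]$value,
    n_trials = n_tr,
    k = length(layout),
    bic = bic(runs[[best]]$value, length(layout), n_tr),
    n_starts = n_starts,
    start_nlls = nlls,
    best_start = best,
    converged = runs[[best]]$convergence == 0
  ), class = "gl_fit")
}

#' @export
print.gl_fit <- function(x, ...) {
  cat(sprintf("<gl_fit: %s | NLL %.3f | BIC %.3f | %d trials | start %d/%d%s>\n",
              x$model, x$nll, x$bic, x$n_trials, x$best_start, x$n_starts,
              if (x$converged) "" else " | NOT CONVERGED"))
  print(round(x$estimates, 4))
  invisible(x)
}

#' @rdname fit_rl
#' @param x A `gl_fit` object.
#' @param ... Unused.
#' @export
tidy.gl_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates), estimate = unname(x$estimates))
}

#' @rdname fit_rl
#' @export
glance.gl_fit <- function(x, ...) {
  tibble::tibble(model = x$model, nll = x$nll, k = x$k,
                 n_trials = x$n_trials, bic = x$bic,
                 converged = x$converged)
}

#' Fit a model to every subject-condition in a cohort
#'
#' Splits the trial table by subject and condition and fits each unit
#' separately (the study design compares fitted parameters between
#' conditions with paired tests, so drug and placebo are independent fits).
#'
#' @param trials Trial tibble with `subject` and `condition` columns.
#' @param model `"qlearning"` or `"opal"`.
#' @param n_starts,include_early_phases Passed to [fit_rl()].
#' @param seed Master seed; each unit receives its own substream.
#' @return A tibble with one row per subject-condition: parameter columns,
#'   `nll`, `k`, `n_trials`, `bic`, `converged`.
#' @export
fit_cohort <- function(trials, model = c("qlearning", "opal"), n_starts = 10,
                       seed = NULL, include_early_phases = FALSE) {
  model <- arg_match(model)
  stopifnot(all(c("subject", "condition") %in% names(trials)))
  units <- dplyr::distinct(trials, .data$subject, .data$condition)
  purrr::pmap_dfr(units, function(subject, condition) {
    tr <- trials[trials$subject == subject & trials$condition == condition, ]
    unit_seed <- if (is.null(seed)) NULL else {
      substream_seed(seed, paste("fit", model, subject, condition))
    }
    fit <- fit_rl(tr, model, n_starts = n_starts, seed = unit_seed,
                  include_early_phases = include_early_phases)
    dplyr::bind_cols(
      tibble::tibble(subject = subject, condition = condition, model = model),
      tibble::as_tibble(as.list(fit$estimates)),
      glance(fit)[c("nll", "k", "n_trials", "bic", "converged")]
    )
  })
}

#' Compare fitted models by mean BIC
#'
#' Aggregates per-unit BICs for each candidate model and declares the model
#' with the lowest mean BIC the winner (an exact tie is reported as a tie,
#' not silently broken). All models must have been fitted to the same set
#' of subject-condition units.
#'
#' @param fits A tibble of per-unit fits covering `>= 2` models (rows from
#'   [fit_cohort()], stacked), with columns `model`, `subject`, `condition`,
#'   `bic`.
#' @param statistic Aggregate per-unit BICs by mean (default) or sum.
#' @return A `gl_model_comparison`: `summary` (per-model mean/sum BIC),
#'   `winner` (`NA` on tie), `tie`, and per-unit BIC differences relative to
#'   the winner's column order.
#' @export
compare_models <- function(fits, statistic = c("mean", "sum")) {
  statistic <- arg_match(statistic)
  stopifnot(all(c("model", "subject", "condition", "bic") %in% names(fits)))
  models <- unique(fits$model)
  units_by_model <- lapply(models, function(m) {
    f <- fits[fits$model == m, ]
    sort(paste(f$subject, f$condition))
  })
  if (length(unique(units_by_model)) != 1L) {
    abort("All models must be fitted to the same subject-condition units.")
  }
  agg <- if (statistic == "mean") mean else sum
  summary <- fits |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(n_units = dplyr::n(),
                     mean_bic = mean(.data$bic),
                     sum_bic = sum(.data$bic), .groups = "drop") |>
    dplyr::arrange(.data$mean_bic)
  stat_col <- if (statistic == "mean") summary$mean_bic else summary$sum_bic
  tie <- sum(stat_col == min(stat_col)) > 1
  winner <- if (tie) NA_character_ else summary$model[which.min(stat_col)]
  wide <- tidyr::pivot_wider(fits[, c("subject", "condition", "model", "bic")],
                             names_from = "model", values_from = "bic")
  structure(list(summary = summary, winner = winner, tie = tie,
                 statistic = statistic, per_unit = wide),
            class = "gl_model_comparison")
}

#' @export
print.gl_model_comparison <- function(x, ...) {
  cat("<gl_model_comparison>\n")
  print(x$summary)
  if (x$tie) cat("Result: exact tie on", x$statistic, "BIC\n")
  else cat("Winner (lowest", paste0(x$statistic, " BIC):"), x$winner, "\n")
  invisible(x)
}

#' @rdname compare_models
#' @param x A `gl_model_comparison`.
#' @param ... Unused.
#' @export
tidy.gl_model_comparison <- function(x, ...) x$summary

#' Population used for recovery validation
#'
#' Recovery exercises ask whether parameters (or the generating model) can
#' be identified from data of the study's size, so they are run in a
#' regime where the task is informative: choice temperatures high enough
#' that behaviour tracks learned values, wide learning-rate dispersion so
#' agents are rankable, and — for the opponent actor model — well-separated
#' Go/NoGo gains and actor rates so its behaviour is not mimicked by the
#' simpler Q model. At near-chance temperatures (as in the behavioural
#' cohort defaults) per-subject learning rates are only weakly identified,
#' which is itself a property worth knowing.
#'
#' @param model `"qlearning"` or `"opal"`.
#' @return A list with named vectors `mean` and `sd` on the transformed
#'   (logit/log) scale, as for [param_population()].
#' @export
recovery_population <- function(model = c("qlearning", "opal")) {
  model <- arg_match(model)
  if (model == "qlearning") {
    list(mean = c(alpha_pos = qlogis(0.4), alpha_neg = qlogis(0.3),
                  beta = log(4), beta_day2 = log(4)),
         sd = c(alpha_pos = 1.5, alpha_neg = 1.5, beta = 0.5,
                beta_day2 = 0.5))
  } else {
    list(mean = c(alpha_g = qlogis(0.5), alpha_n = qlogis(0.15),
                  beta_g = log(3), beta_n = log(0.5),
                  beta_g_day2 = log(3), beta_n_day2 = log(0.5)),
         sd = c(alpha_g = 0.5, alpha_n = 0.5, beta_g = 0.4, beta_n = 0.4,
                beta_g_day2 = 0.4, beta_n_day2 = 0.4))
  }
}

#' Parameter-recovery report
#'
#' Simulates agents with known parameters drawn from a population
#' distribution, refits them, and reports per-parameter bias, RMSE and the
#' true-vs-recovered Spearman correlation pooled over replicates — the
#' standard validation that a fitted model's parameters are interpretable
#' at the study's trial counts.
#'
#' @param model `"qlearning"` or `"opal"`.
#' @param population Population hyperparameters
#'   (default [recovery_population()]).
#' @param n_agents Agents per replicate.
#' @param n_reps Number of replicates (0 returns an empty table).
#' @param seed Integer seed.
#' @param n_starts Starts per fit (fewer than the default 10 keeps
#'   large recovery grids affordable).
#' @param trials_per_pair Learning presentations per pair per block.
#' @param choice_reps Repetitions per transfer pair on the 24-hour phase.
#' @return A tibble: `parameter`, `bias`, `rmse`, `correlation`, `n`.
#' @export
recovery_report <- function(model = c("qlearning", "opal"),
                            population = recovery_population(model),
                            n_agents = 31, n_reps = 1, seed = 1,
                            n_starts = 5, trials_per_pair = 30,
                            choice_reps = 6) {
  model <- arg_match(model)
  layout <- param_layout(model)
  if (n_reps == 0) {
    return(tibble::tibble(parameter = character(), bias = numeric(),
                          rmse = numeric(), correlation = numeric(),
                          n = integer()))
  }
  rows <- purrr::map_dfr(seq_len(n_reps), function(rep) {
    rep_seed <- substream_seed(seed, paste("recovery", model, rep))
    truth <- with_seed(rep_seed, draw_params(model, population, n_agents))
    purrr::map_dfr(seq_len(n_agents), function(i) {
      tp <- params_from_vector(model, unlist(truth[i, names(layout)]))
      sim_seed <- substream_seed(rep_seed, paste("sim", i))
      sim <- with_seed(sim_seed, simulate_agent(
        tp, schedules = dplyr::bind_rows(
          learning_schedule(trials_per_pair = trials_per_pair),
          choice_schedule(reps = choice_reps))))
      fit <- fit_rl(sim, model, n_starts = n_starts,
                    seed = substream_seed(rep_seed, paste("fit", i)))
      tibble::tibble(rep = rep, agent = i, parameter = names(layout),
                     true = unlist(truth[i, names(layout)]),
                     recovered = unname(fit$estimates))
    })
  })
  rows |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      bias = mean(.data$recovered - .data$true),
      rmse = sqrt(mean((.data$recovered - .data$true)^2)),
      correlation = cor(.data$true, .data$recovered, method = "spearman"),
      n = dplyr::n(), .groups = "drop")
}
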