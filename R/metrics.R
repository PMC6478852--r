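#' Percentage of optimal responses in a phase
#'
#' An optimal response selects the symbol more likely to lead to the higher
#' value of the two shown (see [is_optimal()]); the realised outcome is
#' irrelevant. An absent phase yields `NA`, never zero, so missing data
#' propagate to complete-case statistics downstream.
#'
#' @param trials Trial tibble with `phase` and `optimal` columns (one
#'   subject-condition, or any subset you want a single percentage for).
#' @param phase Phase to score.
#' @return A percentage in `[0, 100]`, or `NA_real_` if the phase is empty.
#' @export
accuracy_pct <- function(trials, phase = "choice24h") {
  sel <- trials$phase == phase
  if (!any(sel)) return(NA_real_)
  100 * mean(trials$optimal[sel])
}

#' Percentage of presentations on which a symbol was chosen
#'
#' The number of times the symbol was chosen divided by the number of times
#' it was seen, as a percentage. On the 6-repetition transfer phase each
#' symbol is seen 30 times. A symbol never shown in the phase yields `NA`.
#'
#' @param trials Trial tibble (one subject-condition).
#' @param symbol Symbol A-F.
#' @param phase Phase to score.
#' @return A percentage in `[0, 100]`, or `NA_real_`.
#' @export
choose_pct <- function(trials, symbol, phase = "choice24h") {
  tr <- trials[trials$phase == phase, ]
  seen <- tr$left_symbol == symbol | tr$right_symbol == symbol
  if (!any(seen)) return(NA_real_)
  100 * sum(tr$chosen == symbol & seen) / sum(seen)
}

#' Per-phase choice summary for a cohort
#'
#' For every subject x condition x phase, computes the optimal-response
#' accuracy and, for each symbol, the percentage of presentations on which
#' it was chosen (`choose_X`) and avoided (`avoid_X = 100 - choose_X`).
#' These are the quantities entering the study's t-tests and ANOVAs.
#'
#' @param trials Trial tibble with `subject`, `condition`, `phase`,
#'   `left_symbol`, `right_symbol`, `chosen`, `optimal`.
#' @param phases Phases to summarise (default: the three choice phases).
#' @return A `gl_choice_summary` tibble, one row per subject x condition x
#'   phase: `accuracy`, `choose_A` ... `choose_F`, `avoid_A` ... `avoid_F`.
#' @export
#' @examples
#' set.seed(1)
#' coh <- generate_cohort(cohort_config(n_subjects = 2))
#' choice_summary(coh$trials)
choice_summary <- function(trials,
                           phases = c("choice0", "choice30", "choice24h")) {
  tr <- trials[trials$phase %in% phases, ]
  acc <- tr |>
    dplyr::group_by(.data$subject, .data$condition, .data$phase) |>
    dplyr::summarise(accuracy = 100 * mean(.data$optimal), .groups = "drop")
  long <- purrr::map_dfr(LETTERS[1:6], function(sym) {
    tr |>
      dplyr::filter(.data$left_symbol == sym | .data$right_symbol == sym) |>
      dplyr::group_by(.data$subject, .data$condition, .data$phase) |>
      dplyr::summarise(symbol = sym,
                       choose = 100 * mean(.data$chosen == sym),
                       .groups = "drop")
  })
  wide <- long |>
    dplyr::mutate(avoid = 100 - .data$choose) |>
    tidyr::pivot_wider(names_from = "symbol",
                       values_from = c("choose", "avoid"), names_sep = "_")
  out <- dplyr::left_join(acc, wide,
                          by = c("subject", "condition", "phase")) |>
    dplyr::arrange(.data$subject, .data$condition,
                   match(.data$phase, task_phases))
  class(out) <- c("gl_choice_summary", class(out))
  out
}

# learning-pair membership for thresholding rules
pair_of <- function(left, right) {
  key <- paste0(pmin(left, right), pmax(left, right))
  c(AB = "gain", CD = "look", EF = "loss")[key]
}

#' Select learners by post-hoc accuracy thresholding
#'
#' Reproduces the study's post-hoc learner selection: a subject-condition is
#' retained when its learning-phase accuracy exceeds 60% (strictly) under
#' the chosen rule — overall, on the Gain or Loss pair only, or on the final
#' 10 presentations of the Gain or Loss pair (pooled across the two
#' learning blocks). `"any"` is the union of the five criteria.
#'
#' @param trials Cohort trial tibble.
#' @param rule One of `"overall"`, `"gain_pair"`, `"loss_pair"`,
#'   `"last10_gain"`, `"last10_loss"`, `"any"`.
#' @param threshold Accuracy threshold in percent (default 60, strict).
#' @return A tibble of retained `subject`, `condition` pairs.
#' @export
threshold_learners <- function(trials,
                               rule = c("overall", "gain_pair", "loss_pair",
                                        "last10_gain", "last10_loss", "any"),
                               threshold = 60) {
  rule <- arg_match(rule)
  learn <- trials[trials$phase == "learning", ]
  learn$pair <- pair_of(learn$left_symbol, learn$right_symbol)
  learn <- dplyr::arrange(learn, .data$subject, .data$condition,
                          .data$block, .data$trial_index)

  acc_by <- function(df) {
    df |>
      dplyr::group_by(.data$subject, .data$condition) |>
      dplyr::summarise(acc = 100 * mean(.data$optimal), .groups = "drop")
  }
  last10 <- function(df, which_pair) {
    df |>
      dplyr::filter(.data$pair == which_pair) |>
      dplyr::group_by(.data$subject, .data$condition) |>
      dplyr::slice_tail(n = 10) |>
      dplyr::ungroup()
  }
  acc_for_rule <- function(r) {
    switch(r,
      overall = acc_by(learn),
      gain_pair = acc_by(dplyr::filter(learn, .data$pair == "gain")),
      loss_pair = acc_by(dplyr::filter(learn, .data$pair == "loss")),
      last10_gain = acc_by(last10(learn, "gain")),
      last10_loss = acc_by(last10(learn, "loss"))
    )
  }
  rules <- if (rule == "any") {
    c("overall", "gain_pair", "loss_pair", "last10_gain", "last10_loss")
  } else {
    rule
  }
  kept <- purrr::map_dfr(rules, function(r) {
    a <- acc_for_rule(r)
    a[a$acc > threshold, c("subject", "condition")]
  })
  dplyr::distinct(kept) |> dplyr::arrange(.data$subject, .data$condition)
}

#' Weight-adjusted levodopa dose
#'
#' Divides the administered dose (mg) by body weight (kg) to give mg/kg,
#' the covariate used to probe dose-dependent drug effects.
#'
#' @param meta Subject metadata tibble with `weight_kg` and `dose_mg`
#'   columns (see [generate_cohort()]).
#' @return `meta` with a `dose_per_kg` column appended.
#' @export
#' @examples
#' weight_adjusted_dose(tibble::tibble(weight_kg = 75, dose_mg = 150))
weight_adjusted_dose <- function(meta) {
  stopifnot(all(c("weight_kg", "dose_mg") %in% names(meta)))
  if (any(!is.finite(meta$weight_kg) | meta$weight_kg <= 0)) {
    abort("Body weight must be positive.")
  }
  if (any(meta$dose_mg < 0)) abort("Dose must be non-negative.")
  meta$dose_per_kg <- meta$dose_mg / meta$weight_kg
  meta
}
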