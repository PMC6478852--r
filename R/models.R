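#' Parameters for the dual-learning-rate Q-learning model
#'
#' The model learns an action value Q per symbol from prediction errors
#' `delta = reward - Q`, with separate learning rates for positive
#' (`alpha_pos`) and negative (`alpha_neg`) prediction errors, and chooses
#' between the two displayed symbols by a softmax on Q. Separate softmax
#' inverse temperatures are used for day-1 feedback trials (`beta`) and the
#' day-2 (24-hour) feedback-free choice phase (`beta_day2`): the only
#' parameters identifiable on a feedback-free phase are the inverse
#' temperatures, which is where a drug acting on expression rather than
#' learning would show up.
#'
#' @param alpha_pos,alpha_neg Learning rates in `[0, 1]`.
#' @param beta,beta_day2 Softmax inverse temperatures, `>= 0`.
#' @return An object of class `gl_params` (model `"qlearning"`).
#' @export
#' @examples
#' q_params(0.4, 0.2, beta = 1.5, beta_day2 = 3)
q_params <- function(alpha_pos = 0.3, alpha_neg = 0.3, beta = 1.5,
                     beta_day2 = 3) {
  assert_scalar_number(alpha_pos, "alpha_pos", 0, 1)
  assert_scalar_number(alpha_neg, "alpha_neg", 0, 1)
  assert_scalar_number(beta, "beta", 0)
  assert_scalar_number(beta_day2, "beta_day2", 0)
  structure(list(alpha_pos = alpha_pos, alpha_neg = alpha_neg,
                 beta = beta, beta_day2 = beta_day2),
            class = "gl_params", model = "qlearning")
}

#' Parameters for the opponent actor (OpAL) model
#'
#' OpAL maintains a critic value V per symbol (delta-rule, rate `alpha_c`)
#' and two Hebbian actor weights: a Go weight G potentiated by positive
#' prediction errors (rate `alpha_g`) and a NoGo weight N potentiated by
#' negative prediction errors (rate `alpha_n`). Choice combines the actors
#' as `beta_g * G - beta_n * N`, so the two gains separately control the
#' influence of information learned through positive and negative
#' reinforcement; day-2 gains apply on the 24-hour choice phase.
#'
#' The critic rate is not counted among the model's fitted learning rates;
#' by default it is tied to the actor rates as `(alpha_g + alpha_n) / 2`.
#'
#' @param alpha_g,alpha_n Actor learning rates in `[0, 1]`.
#' @param beta_g,beta_n Day-1 Go/NoGo choice gains, `>= 0`.
#' @param beta_g_day2,beta_n_day2 Day-2 (24-hour phase) gains, `>= 0`.
#' @param alpha_c Critic learning rate in `[0, 1]`, or `NULL` to tie it to
#'   the actor rates.
#' @return An object of class `gl_params` (model `"opal"`).
#' @export
#' @examples
#' opal_params(0.3, 0.3, beta_g = 1, beta_n = 1)
opal_params <- function(alpha_g = 0.3, alpha_n = 0.3, beta_g = 1, beta_n = 1,
                        beta_g_day2 = beta_g, beta_n_day2 = beta_n,
                        alpha_c = NULL) {
  assert_scalar_number(alpha_g, "alpha_g", 0, 1)
  assert_scalar_number(alpha_n, "alpha_n", 0, 1)
  assert_scalar_number(beta_g, "beta_g", 0)
  assert_scalar_number(beta_n, "beta_n", 0)
  assert_scalar_number(beta_g_day2, "beta_g_day2", 0)
  assert_scalar_number(beta_n_day2, "beta_n_day2", 0)
  tied <- is.null(alpha_c)
  if (tied) alpha_c <- (alpha_g + alpha_n) / 2
  assert_scalar_number(alpha_c, "alpha_c", 0, 1)
  structure(list(alpha_g = alpha_g, alpha_n = alpha_n, beta_g = beta_g,
                 beta_n = beta_n, beta_g_day2 = beta_g_day2,
                 beta_n_day2 = beta_n_day2, alpha_c = alpha_c),
            class = "gl_params", model = "opal", alpha_c_tied = tied)
}

#' @export
print.gl_params <- function(x, ...) {
  cat("<gl_params:", attr(x, "model"), "model>\n")
  print(unlist(x))
  invisible(x)
}

#' Registered model names
#' @return Character vector of model names accepted throughout the package.
#' @export
gl_models <- function() c("qlearning", "opal")

#' Softmax choice probabilities
#'
#' Numerically stable softmax over a vector of action values with inverse
#' temperature `beta` (max-subtraction before exponentiation). `beta = 0`
#' gives the uniform distribution.
#'
#' @param values Finite numeric vector of action values or strengths.
#' @param beta Inverse temperature, `>= 0`.
#' @return Probabilities, same length as `values`, summing to 1.
#' @export
#' @examples
#' softmax_probs(c(1, 0), beta = 1)  # c(0.731, 0.269)
softmax_probs <- function(values, beta = 1) {
  if (!all(is.finite(values))) abort("`values` must be finite.")
  assert_scalar_number(beta, "beta", lower = 0)
  z <- beta * values
  e <- exp(z - max(z))
  # floor keeps probabilities strictly positive even when exp underflows;
  # the perturbation is far below the 1e-12 normalisation tolerance
  pmax(e / sum(e), .Machine$double.xmin)
}

#' Initial Q-learning state
#'
#' All six symbols start at Q = 0 (the value of the NOTHING outcome).
#' @return A `gl_state` list with named vector `Q` and last prediction
#'   error `delta`.
#' @export
q_state <- function() {
  structure(list(Q = setNames(numeric(6), LETTERS[1:6]), delta = NA_real_),
            class = "gl_state", model = "qlearning")
}

#' Initial OpAL state
#'
#' Critic values start at 0; both actor weights start at 1 (the conventional
#' OpAL initialisation, which keeps the multiplicative Hebbian updates
#' live).
#' @return A `gl_state` list with named vectors `V`, `G`, `N` and `delta`.
#' @export
opal_state <- function() {
  one <- setNames(rep(1, 6), LETTERS[1:6])
  structure(list(V = setNames(numeric(6), LETTERS[1:6]), G = one, N = one,
                 delta = NA_real_),
            class = "gl_state", model = "opal")
}

#' One Q-learning update
#'
#' Applies `delta = reward - Q[chosen]` with the positive-error rate when
#' `delta > 0` and the negative-error rate otherwise; unchosen symbols are
#' untouched.
#'
#' @param state A `gl_state` from [q_state()].
#' @param chosen Symbol A-F.
#' @param reward Coded reward (-1, 0 or +1).
#' @param params [q_params()].
#' @return The updated state (with `delta` set).
#' @export
q_update <- function(state, chosen, reward, params) {
  stopifnot(attr(state, "model") == "qlearning")
  if (!chosen %in% names(state$Q)) abort("Unknown symbol in `chosen`.")
  delta <- reward - state$Q[[chosen]]
  rate <- if (delta > 0) params$alpha_pos else params$alpha_neg
  state$Q[[chosen]] <- state$Q[[chosen]] + rate * delta
  state$delta <- delta
  state
}

#' One OpAL update
#'
#' Critic: `V += alpha_c * delta`. Actors (Hebbian, gated by the current
#' weight): `G += alpha_g * G * delta`, `N += alpha_n * N * (-delta)`, both
#' floored at 1e-6 so a large single error cannot flip a weight's sign.
#'
#' @inheritParams q_update
#' @param params [opal_params()].
#' @return The updated state (with `delta` set).
#' @export
opal_update <- function(state, chosen, reward, params) {
  stopifnot(attr(state, "model") == "opal")
  if (!chosen %in% names(state$V)) abort("Unknown symbol in `chosen`.")
  delta <- reward - state$V[[chosen]]
  state$V[[chosen]] <- state$V[[chosen]] + params$alpha_c * delta
  state$G[[chosen]] <- max(state$G[[chosen]] + params$alpha_g * state$G[[chosen]] * delta, 1e-6)
  state$N[[chosen]] <- max(state$N[[chosen]] + params$alpha_n * state$N[[chosen]] * (-delta), 1e-6)
  state$delta <- delta
  state
}

phase_is_day2 <- function(phase) phase == "choice24h"

#' Action strength of a symbol in a given phase
#'
#' The quantity entering the (unit-temperature) softmax: `beta * Q` for
#' Q-learning and `beta_g * G - beta_n * N` for OpAL, using day-1
#' parameters on learning/practice and early choice phases and day-2
#' parameters on the 24-hour phase.
#'
#' @param state A `gl_state`.
#' @param symbol Symbol A-F.
#' @param params Matching `gl_params`.
#' @param phase One of practice, learning, choice0, choice30, choice24h.
#' @return A single numeric strength.
#' @export
action_strength <- function(state, symbol, params, phase = "learning") {
  if (!phase %in% task_phases) abort("Unknown phase.")
  day2 <- phase_is_day2(phase)
  if (attr(state, "model") == "qlearning") {
    b <- if (day2) params$beta_day2 else params$beta
    b * state$Q[[symbol]]
  } else {
    bg <- if (day2) params$beta_g_day2 else params$beta_g
    bn <- if (day2) params$beta_n_day2 else params$beta_n
    bg * state$G[[symbol]] - bn * state$N[[symbol]]
  }
}

# select and flag the trials entering the likelihood; practice is never
# modelled, values never update on feedback-free trials
modelled_trials <- function(trials, include_early_phases = FALSE) {
  stopifnot(all(c("phase", "left_symbol", "right_symbol", "chosen") %in% names(trials)))
  keep <- c("learning", "choice24h",
            if (include_early_phases) c("choice0", "choice30"))
  tr <- trials[trials$phase %in% keep, , drop = FALSE]
  if (nrow(tr) == 0) abort("No modellable trials in input.")
  ord <- match(tr$phase, task_phases)
  if (is.unsorted(ord)) {
    abort("Trials must be in chronological phase order (learning before choice phases).")
  }
  syms <- c(tr$left_symbol, tr$right_symbol, tr$chosen)
  if (!all(syms %in% LETTERS[1:6])) abort("Trial table contains unknown symbols.")
  if (any(tr$chosen != tr$left_symbol & tr$chosen != tr$right_symbol)) {
    abort("`chosen` must be one of the displayed symbols.")
  }
  tr$update <- tr$phase == "learning"
  if (any(tr$update & !is.finite(tr$reward))) {
    abort("Learning trials must carry a finite reward.")
  }
  tr$day2 <- phase_is_day2(tr$phase)
  tr
}

#' Negative log-likelihood of a trial sequence under a model
#'
#' Computes `-sum(log P(chosen_t | state_t))` by replaying the trial
#' sequence: values update only on feedback (learning) trials; the 24-hour
#' choice phase uses the day-2 choice parameters. By default the modelled
#' trials are the day-1 learning trials plus the 24-hour choice phase;
#' `include_early_phases = TRUE` additionally scores the 0-minute and
#' 30-minute phases under the day-1 choice parameters with frozen values.
#' The model is position-blind: left/right placement does not enter the
#' likelihood.
#'
#' @param trials Trial tibble with columns `phase`, `left_symbol`,
#'   `right_symbol`, `chosen`, `reward`, in chronological order.
#' @param params A `gl_params` object ([q_params()] or [opal_params()]).
#' @param include_early_phases Score choice0/choice30 too?
#' @return The negative log-likelihood (finite for finite inverse
#'   temperatures).
#' @export
model_nll <- function(trials, params, include_early_phases = FALSE) {
  stopifnot(inherits(params, "gl_params"))
  tr <- modelled_trials(trials, include_early_phases)
  chosen <- match(tr$chosen, LETTERS[1:6]) - 1L
  other_sym <- ifelse(tr$chosen == tr$left_symbol, tr$right_symbol, tr$left_symbol)
  other <- match(other_sym, LETTERS[1:6]) - 1L
  reward <- ifelse(is.na(tr$reward), 0, tr$reward)
  if (attr(params, "model") == "qlearning") {
    q_nll_cpp(chosen, other, reward, tr$update, tr$day2,
              params$alpha_pos, params$alpha_neg, params$beta, params$beta_day2)
  } else {
    opal_nll_cpp(chosen, other, reward, tr$update, tr$day2,
                 params$alpha_g, params$alpha_n, params$alpha_c,
                 params$beta_g, params$beta_n,
                 params$beta_g_day2, params$beta_n_day2)
  }
}

#' Standard trial schedules for one session
#'
#' The study's session structure: a 30-trial practice block, two 90-trial
#' learning blocks (30 per pair), and three feedback-free 90-trial choice
#' phases (immediately after learning, after 30 minutes, and 24 hours
#' later).
#'
#' @param practice Include the practice block?
#' @return A tibble of schedule skeletons for all phases, in chronological
#'   order.
#' @export
standard_schedules <- function(practice = TRUE) {
  dplyr::bind_rows(
    if (practice) practice_schedule(),
    learning_schedule(),
    choice_schedule(phase = "choice0"),
    choice_schedule(phase = "choice30"),
    choice_schedule(phase = "choice24h")
  )
}

#' Simulate one agent through a session
#'
#' Plays a model through the supplied schedules: on practice and learning
#' trials the agent chooses by its softmax, receives a sampled probabilistic
#' outcome, and updates its values; on feedback-free choice phases it
#' chooses from the values frozen at the end of learning (day-2 choice
#' parameters on the 24-hour phase) and no outcome is delivered. Practice
#' uses separate stimuli, so the practice state is discarded before
#' learning.
#'
#' @param params A `gl_params` object.
#' @param symbols Contingency tibble from [gl_symbols()].
#' @param schedules Schedule tibble, e.g. [standard_schedules()].
#' @return A complete, likelihood-scorable trial tibble with `chosen`,
#'   `outcome`, `reward` and `optimal` columns; the final learning state is
#'   attached as attribute `"state"`.
#' @export
#' @examples
#' set.seed(1)
#' sim <- simulate_agent(q_params(beta = 2, beta_day2 = 5))
#' mean(sim$optimal[sim$phase == "choice24h"])
simulate_agent <- function(params, symbols = gl_symbols(),
                           schedules = standard_schedules()) {
  stopifnot(inherits(params, "gl_params"))
  model <- attr(params, "model")
  p_sal <- symbols$p_salient[match(LETTERS[1:6], symbols$symbol)]
  v_sal <- symbols$salient_value[match(LETTERS[1:6], symbols$symbol)]
  out_label <- symbols$salient_outcome[match(LETTERS[1:6], symbols$symbol)]

  sim_feedback <- function(sched) {
    l <- match(sched$left_symbol, LETTERS[1:6]) - 1L
    r <- match(sched$right_symbol, LETTERS[1:6]) - 1L
    if (model == "qlearning") {
      res <- q_sim_learn_cpp(l, r, p_sal, v_sal, params$alpha_pos,
                             params$alpha_neg, params$beta, numeric(6))
    } else {
      res <- opal_sim_learn_cpp(l, r, p_sal, v_sal, params$alpha_g,
                                params$alpha_n, params$alpha_c,
                                params$beta_g, params$beta_n)
    }
    sched$chosen <- LETTERS[1:6][res$chosen + 1L]
    sched$outcome <- ifelse(res$salient, out_label[res$chosen + 1L], "NOTHING")
    sched$reward <- res$reward
    list(trials = sched, final = res)
  }

  sim_choice <- function(sched, final) {
    day2 <- phase_is_day2(sched$phase[1])
    strength <- if (model == "qlearning") {
      b <- if (day2) params$beta_day2 else params$beta
      b * final$Q
    } else {
      bg <- if (day2) params$beta_g_day2 else params$beta_g
      bn <- if (day2) params$beta_n_day2 else params$beta_n
      bg * final$G - bn * final$N
    }
    l <- match(sched$left_symbol, LETTERS[1:6])
    r <- match(sched$right_symbol, LETTERS[1:6])
    p_left <- plogis(strength[l] - strength[r])
    take_left <- runif(nrow(sched)) < p_left
    sched$chosen <- ifelse(take_left, sched$left_symbol, sched$right_symbol)
    sched$outcome <- NA_character_
    sched$reward <- NA_real_
    sched
  }

  pieces <- list()
  final <- NULL
  for (ph in intersect(task_phases, unique(schedules$phase))) {
    sched <- schedules[schedules$phase == ph, , drop = FALSE]
    if (ph %in% c("practice", "learning")) {
      res <- sim_feedback(sched)
      pieces[[ph]] <- res$trials
      if (ph == "learning") final <- res$final
    } else {
      if (is.null(final)) abort("Choice phases require a preceding learning phase.")
      pieces[[ph]] <- sim_choice(sched, final)
    }
  }
  out <- score_optimal(dplyr::bind_rows(pieces))
  attr(out, "state") <- final
  out
}
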