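#' Symbol contingencies for the GainLoss task
#'
#' The task presents three pairs of symbols. In the Gain pair, symbol A leads
#' to a monetary GAIN on 80% of trials (NOTHING otherwise) and symbol B on
#' 20%; in the Look pair, symbols C/D lead to a valueless LOOK outcome on
#' 80%/20% of trials; in the Loss pair, symbol F leads to a monetary LOSS on
#' 80% of trials and symbol E on 20%. Outcomes are coded +1 (GAIN), 0 (LOOK /
#' NOTHING) and -1 (LOSS), so the 20-pence stake is dimensionless.
#'
#' @param condition Condition label; distinct stimulus sets are used per
#'   condition, so the tag is carried on every row.
#' @param conditions Character vector of configured condition labels;
#'   `condition` must be one of them.
#' @return A tibble with one row per symbol: `condition`, `symbol` (A-F),
#'   `pair` (Gain/Look/Loss), `p_salient`, `salient_outcome`, `salient_value`
#'   and `ev` (expected value of choosing the symbol).
#' @export
#' @examples
#' gl_symbols("drug")
gl_symbols <- function(condition = "drug", conditions = c("drug", "placebo")) {
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% conditions) {
    abort(sprintf("Unknown condition tag %s; configured conditions: %s.",
                  deparse(condition), paste(conditions, collapse = ", ")))
  }
  out <- tibble::tibble(
    condition       = condition,
    symbol          = c("A", "B", "C", "D", "E", "F"),
    pair            = rep(c("Gain", "Look", "Loss"), each = 2),
    p_salient       = c(0.8, 0.2, 0.8, 0.2, 0.2, 0.8),
    salient_outcome = rep(c("GAIN", "LOOK", "LOSE"), each = 2),
    salient_value   = rep(c(1, 0, -1), each = 2)
  )
  out$ev <- expected_value(out)
  out
}

#' Expected value of each symbol contingency
#'
#' The expected value is the sum over outcomes of probability times coded
#' value; the complementary outcome is always NOTHING (value 0), so
#' `ev = p_salient * salient_value` (e.g. -0.8 for the 80% LOSS symbol).
#'
#' @param contingencies A contingency tibble as returned by [gl_symbols()]
#'   (needs columns `p_salient` and `salient_value`).
#' @return Numeric vector of expected values, one per row.
#' @export
#' @examples
#' expected_value(gl_symbols())
expected_value <- function(contingencies) {
  stopifnot(all(c("p_salient", "salient_value") %in% names(contingencies)))
  contingencies$p_salient * contingencies$salient_value
}

# strict optimality order A > B > C > D > E > F; rank 1 is best
symbol_rank <- c(A = 1L, B = 2L, C = 3L, D = 4L, E = 5L, F = 6L)

#' Optimal-response coding for a choice between two symbols
#'
#' A selection is optimal when the chosen symbol is more likely to lead to
#' the higher-valued outcome of the two shown, regardless of the outcome
#' actually realised on that trial. The coding implements the strict order
#' A > B > C > D > E > F: Gain symbols beat Look symbols, Look symbols beat
#' Loss symbols, and within the Look pair the 80% LOOK symbol (C) is treated
#' as optimal even though both members have expected value zero.
#'
#' @param left,right Character vectors of symbols (A-F) forming each pair.
#' @param chosen Character vector; must equal `left` or `right` elementwise.
#' @return Logical vector: `TRUE` where the chosen symbol is the
#'   higher-ranked member of its pair.
#' @export
#' @examples
#' is_optimal("A", "B", "A")   # TRUE
#' is_optimal("B", "C", "C")   # FALSE: Gain beats Look
is_optimal <- function(left, right, chosen) {
  bad_symbol <- !(left %in% names(symbol_rank)) |
    !(right %in% names(symbol_rank))
  if (any(bad_symbol)) {
    abort("Symbols must be one of A-F.")
  }
  if (any(chosen != left & chosen != right)) {
    abort("`chosen` must be one of the two symbols shown on each trial.")
  }
  other <- ifelse(chosen == left, right, left)
  symbol_rank[chosen] < symbol_rank[other]
}

# low-overhead constructor: schedules are built in tight simulation loops
new_schedule <- function(phase, block, left, right) {
  n <- length(left)
  tibble::new_tibble(list(
    phase = rep_len(phase, n),
    block = rep_len(as.integer(block), n),
    trial_index = seq_len(n),
    left_symbol = left,
    right_symbol = right
  ), nrow = n)
}

#' Build a learning (or practice) schedule
#'
#' Each learning block presents the three fixed pairs (AB, CD, EF)
#' `trials_per_pair` times each in shuffled order, with left/right screen
#' position randomised independently per trial. The study's learning phase
#' is two blocks of 90 trials (30 per pair); the practice block is a single
#' block with 10 trials per pair.
#'
#' @param n_blocks Number of blocks (`>= 1`).
#' @param trials_per_pair Presentations of each pair per block (`>= 1`).
#' @param phase Phase label, `"learning"` or `"practice"`.
#' @return A schedule tibble with columns `phase`, `block`, `trial_index`
#'   (running within the phase), `left_symbol`, `right_symbol`.
#' @export
#' @examples
#' set.seed(1)
#' nrow(learning_schedule())  # 180
learning_schedule <- function(n_blocks = 2, trials_per_pair = 30,
                              phase = c("learning", "practice")) {
  phase <- arg_match(phase)
  assert_scalar_number(n_blocks, "n_blocks", lower = 1)
  assert_scalar_number(trials_per_pair, "trials_per_pair", lower = 1)
  pairs <- matrix(c("A", "B", "C", "D", "E", "F"), ncol = 2, byrow = TRUE)
  per_block <- 3 * trials_per_pair
  idx <- unlist(lapply(seq_len(n_blocks),
                       function(b) sample(rep(1:3, trials_per_pair))))
  flip <- runif(length(idx)) < 0.5
  left <- ifelse(flip, pairs[idx, 2], pairs[idx, 1])
  right <- ifelse(flip, pairs[idx, 1], pairs[idx, 2])
  new_schedule(phase, rep(seq_len(n_blocks), each = per_block), left, right)
}

#' Build a practice schedule
#'
#' Convenience wrapper for the 30-trial practice block (10 per pair).
#' @param trials_per_pair Presentations of each pair (default 10).
#' @return A schedule tibble (see [learning_schedule()]).
#' @export
practice_schedule <- function(trials_per_pair = 10) {
  learning_schedule(n_blocks = 1, trials_per_pair = trials_per_pair,
                    phase = "practice")
}

#' Build a feedback-free choice (transfer) schedule
#'
#' Choice performance is measured by presenting all symbols in all pairwise
#' combinations (15 unordered pairs) `reps` times each without outcomes;
#' with the default 6 repetitions this gives 90 trials.
#'
#' @param reps Repetitions of each of the 15 pairs (`>= 1`).
#' @param phase Phase label, one of `"choice0"`, `"choice30"`, `"choice24h"`.
#' @return A schedule tibble (see [learning_schedule()]); `block` is 1.
#' @export
#' @examples
#' set.seed(1)
#' nrow(choice_schedule())  # 90
choice_schedule <- function(reps = 6, phase = c("choice24h", "choice0", "choice30")) {
  phase <- arg_match(phase)
  assert_scalar_number(reps, "reps", lower = 1)
  combos <- utils::combn(c("A", "B", "C", "D", "E", "F"), 2)
  idx <- sample(rep(seq_len(ncol(combos)), reps))
  flip <- runif(length(idx)) < 0.5
  left <- ifelse(flip, combos[2, idx], combos[1, idx])
  right <- ifelse(flip, combos[1, idx], combos[2, idx])
  new_schedule(phase, 1L, left, right)
}

#' Sample probabilistic outcomes for chosen symbols
#'
#' Each symbol delivers its salient outcome with probability `p_salient` and
#' NOTHING (reward 0) otherwise. By default draws are i.i.d. Bernoulli per
#' trial; `exact_mix = TRUE` instead shuffles a fixed outcome list per symbol
#' per block whose composition matches the contingency as closely as the
#' count allows (exact 80/20 splits when the presentation count is a
#' multiple of 5).
#'
#' @param trials A tibble with columns `chosen` and `block`.
#' @param symbols Contingency tibble from [gl_symbols()].
#' @param exact_mix Logical; use the fixed-mix mode.
#' @return `trials` with `outcome` (GAIN/LOSE/LOOK/NOTHING) and `reward`
#'   (-1/0/+1) columns filled in.
#' @export
#' @examples
#' set.seed(1)
#' tr <- tibble::tibble(chosen = rep("A", 5), block = 1L)
#' sample_outcomes(tr, gl_symbols())
sample_outcomes <- function(trials, symbols, exact_mix = FALSE) {
  stopifnot(all(c("chosen", "block") %in% names(trials)))
  look <- match(trials$chosen, symbols$symbol)
  if (anyNA(look)) abort("`trials$chosen` contains symbols not in `symbols`.")
  p <- symbols$p_salient[look]
  if (exact_mix) {
    salient <- logical(nrow(trials))
    for (grp in split(seq_len(nrow(trials)),
                      list(trials$chosen, trials$block), drop = TRUE)) {
      n <- length(grp)
      n_sal <- round(symbols$p_salient[match(trials$chosen[grp[1]],
                                             symbols$symbol)] * n)
      salient[grp] <- sample(rep(c(TRUE, FALSE), c(n_sal, n - n_sal)))
    }
  } else {
    salient <- runif(nrow(trials)) < p
  }
  trials$outcome <- ifelse(salient, symbols$salient_outcome[look], "NOTHING")
  trials$reward <- ifelse(salient, symbols$salient_value[look], 0)
  trials
}

#' Sample repeated outcomes for one symbol
#'
#' Single-symbol convenience around [sample_outcomes()], useful for checking
#' empirical outcome frequencies against the programmed contingencies.
#'
#' @param symbols Contingency tibble from [gl_symbols()].
#' @param symbol One of A-F.
#' @param n Number of draws.
#' @return A tibble with `outcome` and `reward` columns, `n` rows.
#' @export
#' @examples
#' set.seed(1)
#' mean(sample_outcome(gl_symbols(), "A", 1000)$outcome == "GAIN")
sample_outcome <- function(symbols, symbol, n = 1) {
  tr <- tibble::tibble(chosen = rep(symbol, n), block = 1L)
  sample_outcomes(tr, symbols)[, c("outcome", "reward")]
}

#' Add the optimal-response flag to a trial table
#'
#' @param trials A tibble with `left_symbol`, `right_symbol`, `chosen`.
#' @return `trials` with a logical `optimal` column (see [is_optimal()]).
#' @export
score_optimal <- function(trials) {
  trials$optimal <- unname(is_optimal(trials$left_symbol, trials$right_symbol,
                                      trials$chosen))
  trials
}
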