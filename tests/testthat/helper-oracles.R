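# Independent oracles and small fixtures, written from first principles so
# they share no code path with the implementation under test.

# brute-force sequential choice likelihood: plain arithmetic, no package
# helpers, no numerical-stability tricks (fine for the short sequences and
# moderate temperatures used in tests)
nll_brute <- function(trials, params) {
  model <- attr(params, "model")
  syms <- c("A", "B", "C", "D", "E", "F")
  Q <- setNames(numeric(6), syms)
  V <- Q; G <- setNames(rep(1, 6), syms); N <- G
  keep <- trials$phase %in% c("learning", "choice24h")
  tr <- trials[keep, , drop = FALSE]
  total <- 0
  for (i in seq_len(nrow(tr))) {
    ch <- tr$chosen[i]
    ot <- if (ch == tr$left_symbol[i]) tr$right_symbol[i] else tr$left_symbol[i]
    day2 <- tr$phase[i] == "choice24h"
    if (model == "qlearning") {
      b <- if (day2) params$beta_day2 else params$beta
      p <- exp(b * Q[ch]) / (exp(b * Q[ch]) + exp(b * Q[ot]))
    } else {
      bg <- if (day2) params$beta_g_day2 else params$beta_g
      bn <- if (day2) params$beta_n_day2 else params$beta_n
      sc <- bg * G[ch] - bn * N[ch]
      so <- bg * G[ot] - bn * N[ot]
      p <- exp(sc) / (exp(sc) + exp(so))
    }
    total <- total - log(unname(p))
    if (tr$phase[i] == "learning") {
      r <- tr$reward[i]
      if (model == "qlearning") {
        d <- r - Q[ch]
        Q[ch] <- Q[ch] + (if (d > 0) params$alpha_pos else params$alpha_neg) * d
      } else {
        d <- r - V[ch]
        V[ch] <- V[ch] + params$alpha_c * d
        G[ch] <- max(G[ch] + params$alpha_g * G[ch] * d, 1e-6)
        N[ch] <- max(N[ch] + params$alpha_n * N[ch] * (-d), 1e-6)
      }
    }
  }
  total
}

# Monte-Carlo marginal-likelihood oracle for the JZS Bayes factor:
# BF10 = E_{delta ~ Cauchy(0, r)}[ t-likelihood(t | delta) ] / t-likelihood(t | 0)
bf10_mc <- function(t, n, r = 0.707, n_draws = 2e5, seed = 99) {
  withr::with_seed(seed, {
    delta <- rcauchy(n_draws, 0, r)
    num <- mean(suppressWarnings(dt(t, df = n - 1, ncp = delta * sqrt(n))))
    num / dt(t, df = n - 1)
  })
}

# hand-built trial tibble: chosen/reward supplied explicitly
toy_trials <- function(phase, left, right, chosen, reward = NA_real_) {
  tibble::tibble(phase = phase, block = 1L,
                 trial_index = seq_along(left),
                 left_symbol = left, right_symbol = right, chosen = chosen,
                 outcome = NA_character_, reward = reward)
}

# random modellable trial sequence (learning then choice24h) for property
# tests; rewards drawn from {-1, 0, 1}
random_trials <- function(n_learn, n_choice) {
  syms <- c("A", "B", "C", "D", "E", "F")
  pick_pair <- function(n, pairs) {
    idx <- sample(nrow(pairs), n, replace = TRUE)
    flip <- runif(n) < 0.5
    data.frame(left = ifelse(flip, pairs[idx, 2], pairs[idx, 1]),
               right = ifelse(flip, pairs[idx, 1], pairs[idx, 2]))
  }
  learn_pairs <- matrix(syms, ncol = 2, byrow = TRUE)
  lp <- pick_pair(n_learn, learn_pairs)
  all_pairs <- t(combn(syms, 2))
  cp <- pick_pair(n_choice, all_pairs)
  chosen_l <- ifelse(runif(n_learn) < 0.5, lp$left, lp$right)
  chosen_c <- ifelse(runif(n_choice) < 0.5, cp$left, cp$right)
  dplyr::bind_rows(
    toy_trials("learning", lp$left, lp$right, chosen_l,
               sample(c(-1, 0, 1), n_learn, replace = TRUE)),
    toy_trials("choice24h", cp$left, cp$right, chosen_c)
  )
}

random_q_params <- function() {
  q_params(runif(1), runif(1), runif(1, 0, 5), runif(1, 0, 5))
}

random_opal_params <- function() {
  opal_params(runif(1), runif(1), runif(1, 0, 3), runif(1, 0, 3),
              runif(1, 0, 3), runif(1, 0, 3))
}
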