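test_that("softmax probabilities are correct and stable", {
  expect_equal(softmax_probs(c(0.3, 0.3), 2), c(0.5, 0.5))
  expect_equal(softmax_probs(c(5, -2), 0), c(0.5, 0.5))
  expect_equal(softmax_probs(c(1, 0), 1),
               c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  # extreme values must not overflow
  expect_equal(sum(softmax_probs(c(1000, -1000), 1)), 1)
  expect_error(softmax_probs(c(1, 0), -1), "beta")
  expect_error(softmax_probs(c(Inf, 0), 1), "finite")
})

test_that("softmax always normalises to 1 within 1e-12", {
  withr::with_seed(3, {
    for (i in 1:200) {
      v <- rnorm(sample(2:6, 1), sd = 10)
      p <- softmax_probs(v, runif(1, 0, 20))
      expect_lt(abs(sum(p) - 1), 1e-12)
      expect_true(all(p > 0))
    }
  })
})

test_that("Q updates apply the signed learning rates", {
  st <- q_state()
  p <- q_params(alpha_pos = 0.5, alpha_neg = 0.25, beta = 1, beta_day2 = 1)
  up <- q_update(st, "A", 1, p)
  expect_equal(up$Q[["A"]], 0.5)
  expect_equal(up$delta, 1)
  expect_equal(up$Q[c("B", "C", "D", "E", "F")], st$Q[c("B", "C", "D", "E", "F")])
  same <- q_update(st, "A", 0, p)       # delta = 0: no change
  expect_equal(same$Q, st$Q)
  dn <- q_update(st, "B", -1, p)
  expect_equal(dn$Q[["B"]], -0.25)
})

test_that("Q values stay in [-1, 1] for admissible parameters", {
  withr::with_seed(11, {
    for (i in 1:30) {
      p <- random_q_params()
      st <- q_state()
      for (t in 1:100) {
        st <- q_update(st, sample(LETTERS[1:6], 1),
                       sample(c(-1, 0, 1), 1), p)
      }
      expect_true(all(st$Q >= -1 & st$Q <= 1))
    }
  })
})

test_that("OpAL updates follow the critic/actor equations", {
  st <- opal_state()
  p <- opal_params(alpha_g = 0.3, alpha_n = 0.2, beta_g = 1, beta_n = 1,
                   alpha_c = 0.1)
  up <- opal_update(st, "A", 1, p)
  expect_equal(up$V[["A"]], 0.1)
  expect_equal(up$G[["A"]], 1.3)        # 1 + 0.3 * 1 * 1
  expect_equal(up$N[["A"]], 1 - 0.2)    # 1 + 0.2 * 1 * (-1)
  # reward equal to the critic value leaves the state unchanged
  st2 <- st; st2$V[["B"]] <- 0.4
  attr(st2, "model") <- "opal"
  same <- opal_update(st2, "B", 0.4, p)
  expect_equal(same$V, st2$V)
  expect_equal(same$G, st2$G)
  expect_equal(same$N, st2$N)
  # actors stay positive even under extreme errors
  pd <- opal_params(alpha_g = 1, alpha_n = 1, beta_g = 1, beta_n = 1,
                    alpha_c = 1)
  hit <- opal_update(opal_state(), "A", -1, pd)
  expect_gte(hit$G[["A"]], 1e-6)
})

test_that("tied critic rate defaults to the actor-rate mean", {
  p <- opal_params(alpha_g = 0.4, alpha_n = 0.2)
  expect_equal(p$alpha_c, 0.3)
  expect_equal(opal_params(0.4, 0.2, alpha_c = 0.05)$alpha_c, 0.05)
})

test_that("action strengths switch to day-2 parameters on the 24-h phase", {
  p <- opal_params(alpha_g = 0.3, alpha_n = 0.3, beta_g = 1, beta_n = 1,
                   beta_g_day2 = 4, beta_n_day2 = 2)
  st <- opal_state()
  expect_equal(action_strength(st, "A", p, "learning"), 0)  # G = N, equal gains
  st$G[["A"]] <- 2
  expect_equal(action_strength(st, "A", p, "learning"), 1)  # 1*2 - 1*1
  expect_equal(action_strength(st, "A", p, "choice24h"), 4 * 2 - 2 * 1)
  qp <- q_params(beta = 1, beta_day2 = 5)
  qs <- q_state(); qs$Q[["A"]] <- 0.5
  expect_equal(action_strength(qs, "A", qp, "learning"), 0.5)
  expect_equal(action_strength(qs, "A", qp, "choice24h"), 2.5)
  expect_error(action_strength(qs, "A", qp, "day3"), "phase")
})

test_that("zero inverse temperatures give T * log(2) likelihood", {
  withr::with_seed(5, {
    tr <- random_trials(20, 15)
    expect_equal(model_nll(tr, q_params(0.3, 0.3, 0, 0)), 35 * log(2))
    expect_equal(model_nll(tr, opal_params(0.3, 0.3, 0, 0, 0, 0)),
                 35 * log(2))
  })
})

test_that("recursive likelihood equals brute-force unrolling to 1e-10", {
  withr::with_seed(8, {
    for (i in 1:25) {
      tr <- random_trials(sample(1:3, 1), sample(1:2, 1))  # <= 5 trials
      qp <- random_q_params()
      expect_equal(model_nll(tr, qp), nll_brute(tr, qp), tolerance = 1e-10)
      op <- random_opal_params()
      expect_equal(model_nll(tr, op), nll_brute(tr, op), tolerance = 1e-10)
    }
    # and on a study-length sequence
    tr <- random_trials(180, 90)
    qp <- random_q_params()
    expect_equal(model_nll(tr, qp), nll_brute(tr, qp), tolerance = 1e-8)
  })
})

test_that("likelihood is blind to left/right position", {
  withr::with_seed(9, {
    tr <- random_trials(40, 20)
    swapped <- tr
    swapped$left_symbol <- tr$right_symbol
    swapped$right_symbol <- tr$left_symbol
    p <- random_q_params()
    expect_identical(model_nll(tr, p), model_nll(swapped, p))
  })
})

test_that("likelihood rejects malformed trial tables", {
  tr <- toy_trials("learning", "A", "B", "A", 1)
  bad <- tr; bad$chosen <- "C"
  expect_error(model_nll(bad, q_params()), "displayed")
  out_of_order <- dplyr::bind_rows(
    toy_trials("choice24h", "A", "F", "A"),
    toy_trials("learning", "A", "B", "A", 1))
  expect_error(model_nll(out_of_order, q_params()), "order")
  expect_error(model_nll(toy_trials("practice", "A", "B", "A", 1),
                         q_params()), "modellable")
})

test_that("simulated agents behave lawfully at the extremes", {
  withr::with_seed(21, {
    # near-greedy agent: A chosen almost always against B late in learning
    sim <- simulate_agent(q_params(0.5, 0.5, beta = 20, beta_day2 = 20))
    learn <- sim[sim$phase == "learning" & sim$block == 2, ]
    gain <- learn[pmin(learn$left_symbol, learn$right_symbol) == "A" &
                    pmax(learn$left_symbol, learn$right_symbol) == "B", ]
    expect_gt(mean(gain$chosen == "A"), 0.9)
    # random agent: chance accuracy on the 24-h phase
    sims <- purrr::map_dfr(1:20, ~ simulate_agent(q_params(0.3, 0.3, 0, 0)))
    expect_equal(accuracy_pct(sims, "choice24h"), 50, tolerance = 5)
  })
})

test_that("choice-phase records carry no outcome and no reward", {
  withr::with_seed(2, {
    sim <- simulate_agent(q_params())
    ch <- sim[sim$phase %in% c("choice0", "choice30", "choice24h"), ]
    expect_true(all(is.na(ch$outcome)))
    expect_true(all(is.na(ch$reward)))
    le <- sim[sim$phase %in% c("practice", "learning"), ]
    expect_true(all(le$reward %in% c(-1, 0, 1)))
  })
})

test_that("24-h choice rates increase with expected value when beta > 0", {
  withr::with_seed(14, {
    sims <- purrr::map_dfr(1:25, function(i) {
      sim <- simulate_agent(q_params(0.4, 0.3, beta = 2, beta_day2 = 4))
      sim$subject <- i; sim$condition <- "drug"
      sim
    })
    cs <- choice_summary(sims, phases = "choice24h")
    mean_choose <- colMeans(cs[paste0("choose_", LETTERS[1:6])])
    ev_order <- c("F", "E", "D", "C", "B", "A")  # ascending value, C/D tied
    ranked <- mean_choose[paste0("choose_", ev_order)]
    expect_equal(cor(ranked, seq_along(ranked), method = "spearman"), 1,
                 tolerance = 0.05)
  })
})

test_that("simulate-then-score prefers the generating parameters to chance", {
  withr::with_seed(31, {
    p <- q_params(0.4, 0.3, beta = 5, beta_day2 = 5)
    worse <- 0
    for (i in 1:5) {
      sim <- simulate_agent(p)
      nll_true <- model_nll(sim, p)
      nll_chance <- model_nll(sim, q_params(0.4, 0.3, 0, 0))
      worse <- worse + (nll_true < nll_chance)
    }
    expect_gte(worse, 4)
  })
})
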