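test_that("paired t matches the closed form on a 3-pair fixture", {
  y <- c(0, 0, 0)
  x <- c(1, 2, 3)                      # differences 1, 2, 3: mean 2, sd 1
  tt <- paired_ttest(x, y, bayes = FALSE)
  expect_equal(tt$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(tt$df, 2)
  expect_equal(tt$d, 2 * sqrt(3) / sqrt(3), tolerance = 1e-10)
  expect_equal(tt$mean_diff, 2)
  # CI from the t quantiles: mean +/- t_{.975, 2} * se
  se <- 1 / sqrt(3)
  expect_equal(tt$ci, 2 + c(-1, 1) * qt(0.975, 2) * se, tolerance = 1e-10)
})

test_that("degenerate paired inputs are refused", {
  expect_error(paired_ttest(1:5, 1:5), "zero variance")
  expect_error(paired_ttest(1, 1), "2 complete pairs")
  expect_error(paired_ttest(1:4, 1:5), "same length")
})

test_that("Cohen's d for the paired design is t over sqrt(n)", {
  # the study's printed accuracy row: t(30) = 0.906 gives d = 0.163
  expect_equal(round(0.906 / sqrt(31), 3), 0.163)
  withr::with_seed(22, {
    x <- rnorm(31, 0.3); y <- rnorm(31)
    tt <- paired_ttest(x, y, bayes = FALSE)
    expect_equal(tt$d, tt$t / sqrt(31))
  })
})

test_that("JZS Bayes factor reproduces the published benchmark values", {
  expect_equal(jzs_bf01(0.906, 31, 0.707), 3.581, tolerance = 5e-4)
  expect_equal(jzs_bf01(1.771, 31, 0.707), 1.301, tolerance = 5e-4)
  expect_equal(jzs_bf01(-1.771, 31, 0.707), jzs_bf01(1.771, 31, 0.707))
})

test_that("BF orientation identity and monotonicity hold", {
  for (t in c(0, 0.5, 1.2, 2.5)) {
    expect_equal(jzs_bf01(t, 31) * jzs_bf10(t, 31), 1, tolerance = 1e-9)
  }
  ts <- seq(0, 4, by = 0.5)
  bfs <- vapply(ts, jzs_bf01, numeric(1), n = 31)
  expect_true(all(diff(bfs) < 0))
  expect_gt(jzs_bf01(0, 31), 1)
})

test_that("quadrature agrees with a Monte-Carlo marginal-likelihood oracle", {
  for (t in c(0, 0.906)) {
    expect_equal(jzs_bf10(t, 31), bf10_mc(t, 31), tolerance = 0.01)
  }
})

test_that("posterior effect summaries are symmetric, accurate and stable", {
  p0 <- posterior_effect(0, 31)
  expect_equal(p0$median, 0, tolerance = 1e-8)
  expect_equal(p0$ci[1], -p0$ci[2], tolerance = 1e-6)
  # the study's accuracy row: posterior median 0.148 at t = 0.906, n = 31
  p <- posterior_effect(0.906, 31)
  expect_equal(p$median, 0.148, tolerance = 0.01)
  expect_equal(p$ci, c(-0.186, 0.482), tolerance = 0.02)
  # grid refinement is converged
  fine <- posterior_effect(0.906, 31, grid_points = 20001)
  expect_equal(p$median, fine$median, tolerance = 1e-4)
  # prior washout: median approaches t/sqrt(n) = d as n grows
  big <- posterior_effect(0.3 * sqrt(500), 500)
  expect_equal(big$median, 0.3, tolerance = 0.01)
})

test_that("repeated-measures ANOVA reproduces the design degrees of freedom", {
  withr::with_seed(23, {
    d <- tidyr::expand_grid(subject = 1:30,
                            time = c("t0", "t30", "t24h"),
                            drug = c("drug", "placebo"))
    d$y <- rnorm(nrow(d))
  })
  a <- rm_anova(d, "y", "subject", c("time", "drug"))
  tab <- tidy(a)
  expect_equal(tab$df1, c(2, 1, 2))
  expect_equal(tab$df2, c(58, 29, 58))
  expect_true(all(tab$pes >= 0 & tab$pes <= 1))
  # epsilon bounds: 1/(k-1) <= GG epsilon <= 1
  expect_true(all(tab$gg_epsilon[c(1, 3)] >= 0.5 - 1e-10))
  expect_true(all(tab$gg_epsilon <= 1 + 1e-10))
  # two-level factor: sphericity trivially holds
  expect_equal(tab$gg_epsilon[2], 1)
  expect_true(is.na(tab$mauchly_p[2]))
})

test_that("ANOVA agrees with the base multivariate-lm machinery", {
  withr::with_seed(24, {
    n <- 18
    Y <- matrix(rnorm(n * 6), n)
    d <- tidyr::expand_grid(subject = seq_len(n), time = c("a", "b", "c"),
                            drug = c("d", "p"))
    d$y <- as.vector(t(Y))  # row-major: subject-major ordering
  })
  a <- tidy(rm_anova(d, "y", "subject", c("time", "drug")))
  colnames(Y) <- paste0("c", 1:6)
  mlm <- lm(Y ~ 1)
  idata <- data.frame(time = factor(rep(c("a", "b", "c"), each = 2)),
                      drug = factor(rep(c("d", "p"), 3)))
  ref_time <- anova(mlm, M = ~time, X = ~1, idata = idata, test = "Spherical")
  expect_equal(a$F[1], ref_time$F[1], tolerance = 1e-8)
  expect_equal(a$p[1], ref_time$`Pr(>F)`[1], tolerance = 1e-8)
  expect_equal(a$p_gg[1], ref_time$`G-G Pr`[1], tolerance = 1e-8)
  m <- mauchly.test(mlm, M = ~time, X = ~1, idata = idata)
  expect_equal(a$mauchly_p[1], m$p.value, tolerance = 1e-8)
  ref_int <- anova(mlm, M = ~time * drug, X = ~time + drug, idata = idata,
                   test = "Spherical")
  expect_equal(a$F[3], ref_int$F[1], tolerance = 1e-8)
  expect_equal(a$p_gg[3], ref_int$`G-G Pr`[1], tolerance = 1e-8)
})

test_that("a 2x2 within design reproduces F = t^2 for each main effect", {
  withr::with_seed(25, {
    d <- tidyr::expand_grid(subject = 1:16, cond = c("drug", "placebo"),
                            choice = c("chooseA", "avoidF"))
    d$y <- rnorm(nrow(d), mean = ifelse(d$cond == "drug", 0.3, 0))
  })
  a <- tidy(rm_anova(d, "y", "subject", c("cond", "choice")))
  agg <- d |>
    dplyr::group_by(subject, cond) |>
    dplyr::summarise(y = mean(y), .groups = "drop") |>
    tidyr::pivot_wider(names_from = cond, values_from = y)
  tt <- paired_ttest(agg$drug, agg$placebo, bayes = FALSE)
  expect_equal(a$F[a$effect == "cond"], tt$t^2, tolerance = 1e-8)
})

test_that("an outcome identical across conditions gives F = 0", {
  d <- tidyr::expand_grid(subject = 1:10, cond = c("drug", "placebo"))
  base <- rnorm(10)
  d$y <- base[d$subject]  # same value under both conditions
  a <- tidy(rm_anova(d, "y", "subject", "cond"))
  expect_equal(a$F[1], 0)
})

test_that("ANOVA drops incomplete subjects and rejects duplicates", {
  d <- tidyr::expand_grid(subject = 1:12, cond = c("drug", "placebo"))
  d$y <- rnorm(nrow(d))
  d_miss <- d[-1, ]  # subject 1 loses a cell
  a <- rm_anova(d_miss, "y", "subject", "cond")
  expect_equal(a$n_subjects, 11)
  expect_equal(a$dropped, 1)
  expect_error(rm_anova(dplyr::bind_rows(d, d[1, ]), "y", "subject", "cond"),
               "Duplicated")
})

test_that("exact binomial conventions behave as documented", {
  expect_equal(binomial_two_sided(3, 3, 0.5, "minlike"), 0.25)
  expect_equal(binomial_two_sided(3, 3, 0.5, "doubling"), 0.25)
  expect_equal(binomial_two_sided(2, 4, 0.5), 1)
  # the blinding test: 17/29 correct guesses is nowhere near significance
  expect_equal(binomial_two_sided(17, 29, 0.5, "minlike"), 0.4583,
               tolerance = 1e-4)
  expect_equal(binomial_two_sided(17, 29, 0.5, "doubling"), 0.4583,
               tolerance = 1e-4)
  # minlike matches the base exact test across asymmetric cases
  for (case in list(c(3, 10, 0.3), c(8, 12, 0.5), c(2, 20, 0.25))) {
    expect_equal(binomial_two_sided(case[1], case[2], case[3], "minlike"),
                 binom.test(case[1], case[2], case[3])$p.value,
                 tolerance = 1e-10)
  }
})

test_that("dose-response regression reports r-squared and overall p", {
  dose <- seq(1.5, 3, length.out = 20)
  exact <- dose_response(dose, 2 * dose, degree = 1)
  expect_equal(exact$r_squared, 1)
  constant <- dose_response(dose, rep(5, 20), degree = 1)
  expect_equal(constant$r_squared, 0)
  expect_equal(constant$p_value, 1)
  expect_error(dose_response(1:2, 1:2, degree = 1), "Too few")
  expect_error(dose_response(dose, 2 * dose, degree = 3), "degree")
})

test_that("dose-response p-values are calibrated under the null", {
  withr::with_seed(26, {
    ps <- replicate(300, dose_response(runif(31, 1.5, 3),
                                       rnorm(31), 1)$p_value)
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
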