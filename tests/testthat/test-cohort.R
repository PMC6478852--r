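test_that("subject parameter draws respect the crossover coupling", {
  # zero dispersion: every subject identical
  pop <- param_population("qlearning")
  pop$sd[] <- 0
  cfg <- cohort_config(n_subjects = 5, population = pop, seed = 2)
  pars <- draw_subject_params(cfg)
  expect_equal(nrow(pars), 10)
  expect_equal(dplyr::n_distinct(round(pars$alpha_pos, 12)), 1)
  # zero drug effect: drug and placebo identical within subject
  cfg2 <- cohort_config(n_subjects = 6, seed = 3)
  p2 <- draw_subject_params(cfg2)
  wide <- tidyr::pivot_wider(p2, names_from = condition,
                             values_from = alpha_pos:beta_day2)
  expect_equal(wide$beta_day2_drug, wide$beta_day2_placebo)
  expect_equal(wide$alpha_pos_drug, wide$alpha_pos_placebo)
})

test_that("a log-scale day-2 shift multiplies beta_day2 by its exponential", {
  cfg <- cohort_config(n_subjects = 500, drug_effect = c(beta_day2 = 1),
                       seed = 4)
  pars <- draw_subject_params(cfg)
  wide <- tidyr::pivot_wider(pars[c("subject", "condition", "beta_day2")],
                             names_from = condition, values_from = beta_day2)
  # the shift acts on log beta_day2, so the within-subject ratio is exactly e
  expect_equal(wide$drug / wide$placebo, rep(exp(1), 500))
  expect_equal(mean(wide$drug) / mean(wide$placebo), exp(1), tolerance = 1e-6)
  expect_error(cohort_config(drug_effect = c(beta = 1)), "day-2")
})

test_that("generated cohorts have the full crossover structure", {
  coh <- generate_cohort(cohort_config(n_subjects = 31, seed = 6))
  units <- dplyr::distinct(coh$trials, subject, condition)
  expect_equal(nrow(units), 62)
  counts <- dplyr::count(coh$trials, subject, condition, phase)
  expect_true(all(counts$n[counts$phase == "choice24h"] == 90))
  expect_true(all(counts$n[counts$phase == "learning"] == 180))
  expect_true(all(counts$n[counts$phase == "practice"] == 30))
  # schedule invariants hold for every generated unit
  one <- coh$trials[coh$trials$subject == 17 &
                      coh$trials$condition == "drug", ]
  ckey <- with(one[one$phase == "choice24h", ],
               paste0(pmin(left_symbol, right_symbol),
                      pmax(left_symbol, right_symbol)))
  expect_true(all(table(ckey) == 6))
  expect_equal(length(unique(ckey)), 15)
  lkey <- with(one[one$phase == "learning", ],
               paste0(pmin(left_symbol, right_symbol),
                      pmax(left_symbol, right_symbol)))
  expect_setequal(unique(lkey), c("AB", "CD", "EF"))
  # condition order is counterbalanced
  expect_equal(sum(coh$meta$order == "drug_first"), 16)
  # metadata are plausible
  expect_true(all(coh$meta$weight_kg >= 40))
  expect_true(all(coh$meta$moca <= 30))
})

test_that("cohort generation is bit-for-bit reproducible from its seed", {
  a <- generate_cohort(cohort_config(n_subjects = 3, seed = 99))
  b <- generate_cohort(cohort_config(n_subjects = 3, seed = 99))
  expect_identical(a$trials, b$trials)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(cohort_config(n_subjects = 3, seed = 100))
  expect_false(identical(a$trials, c$trials))
})

test_that("cohorts round-trip losslessly through CSV", {
  coh <- generate_cohort(cohort_config(n_subjects = 2, seed = 12))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$trials), as.data.frame(coh$trials))
  expect_equal(as.data.frame(back$meta), as.data.frame(coh$meta),
               tolerance = 1e-12)
  expect_equal(back$truth$beta_day2, coh$truth$beta_day2, tolerance = 1e-12)
})

test_that("malformed cohort files fail with row diagnostics", {
  coh <- generate_cohort(cohort_config(n_subjects = 2, seed = 13))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  tr <- readr::read_csv(file.path(dir, "trials.csv"), show_col_types = FALSE)
  tr$chosen[5] <- "G"
  readr::write_csv(tr, file.path(dir, "trials.csv"), na = "")
  expect_error(read_cohort(dir), "row\\(s\\) 5")
  expect_error(read_cohort(withr::local_tempdir()), "trials.csv")
})

test_that("missingness removes whole phases at the configured rate", {
  coh <- generate_cohort(cohort_config(n_subjects = 31, missingness = 0.1,
                                       seed = 14))
  counts <- dplyr::count(coh$trials, subject, condition, phase)
  present <- sum(counts$phase %in% c("choice0", "choice30", "choice24h"))
  total <- 31 * 2 * 3
  missing_frac <- 1 - present / total
  # 3-sigma binomial band around the 10% target
  expect_lt(abs(missing_frac - 0.1), 3 * sqrt(0.1 * 0.9 / total))
  # absent, not zero-filled: no phase has fewer than its full trial count
  expect_true(all(counts$n[counts$phase == "choice24h"] == 90))
  # learning data are never removed
  expect_equal(sum(counts$phase == "learning"), 62)
})

test_that("null cohorts favour the null on the 24-hour accuracy contrast", {
  withr::with_seed(27, {
    bfs <- purrr::map_dbl(1:12, function(i) {
      coh <- generate_cohort(cohort_config(n_subjects = 31, seed = 3000 + i))
      cs <- choice_summary(coh$trials, phases = "choice24h")
      wide <- tidyr::pivot_wider(cs[c("subject", "condition", "accuracy")],
                                 names_from = condition,
                                 values_from = accuracy)
      tt <- paired_ttest(wide$drug, wide$placebo, bayes = FALSE)
      jzs_bf01(tt$t, tt$n)
    })
  })
  expect_gt(mean(bfs > 1), 0.5)
})

test_that("a day-2 temperature boost shows up in fitted parameters", {
  fit_shift <- function(effect, seed) {
    coh <- generate_cohort(cohort_config(
      n_subjects = 10, drug_effect = c(beta_day2 = effect), seed = seed))
    fits <- fit_cohort(coh$trials, "qlearning", n_starts = 3, seed = seed)
    wide <- tidyr::pivot_wider(fits[c("subject", "condition", "beta_day2")],
                               names_from = condition,
                               values_from = beta_day2)
    mean(log(wide$drug) - log(wide$placebo))
  }
  null_shift <- fit_shift(0, 41)
  big_shift <- fit_shift(1.5, 41)
  expect_gt(big_shift, null_shift + 0.5)
})
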