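#' Paired t-test with effect size and Bayesian companion
#'
#' The study's workhorse test: a two-sided paired t-test on within-subject
#' differences, reported with Cohen's d for the paired design
#' (`d = t / sqrt(n)`), the 95% confidence interval of the mean difference,
#' and — unless `bayes = FALSE` — the JZS Bayes factor `BF01` and the
#' posterior median / 95% credible interval of the standardised effect
#' under a Cauchy prior.
#'
#' @param x,y Paired numeric vectors (e.g. drug and placebo scores);
#'   incomplete pairs are dropped.
#' @param prior_scale Cauchy prior width for the Bayesian part.
#' @param bayes Compute the Bayesian companion quantities?
#' @return A `gl_ttest` object with fields `t`, `df`, `p`, `d`, `ci`,
#'   `mean_diff`, `n`, and (if requested) `bf01`, `posterior_median`,
#'   `credible_interval`. Methods: [tidy()], [glance()].
#' @export
#' @examples
#' set.seed(1)
#' paired_ttest(rnorm(31, 0.2), rnorm(31))
paired_ttest <- function(x, y, prior_scale = 0.707, bayes = TRUE) {
  if (length(x) != length(y)) abort("`x` and `y` must be the same length.")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) abort("Need at least 2 complete pairs.")
  if (sd(x - y) == 0) {
    abort("Differences have zero variance; the paired t-test is degenerate.")
  }
  tt <- t.test(x, y, paired = TRUE)
  t_stat <- unname(tt$statistic)
  out <- list(
    t = t_stat, df = unname(tt$parameter), p = tt$p.value,
    d = t_stat / sqrt(n), mean_diff = unname(tt$estimate),
    ci = as.numeric(tt$conf.int), n = n, prior_scale = prior_scale
  )
  if (bayes) {
    out$bf01 <- jzs_bf01(t_stat, n, prior_scale)
    post <- posterior_effect(t_stat, n, prior_scale)
    out$posterior_median <- post$median
    out$credible_interval <- post$ci
  }
  structure(out, class = "gl_ttest")
}

#' @export
print.gl_ttest <- function(x, ...) {
  cat(sprintf("Paired t-test: t(%d) = %.3f, p = %.4f, d = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$df, x$t, x$p, x$d, x$ci[1], x$ci[2]))
  if (!is.null(x$bf01)) {
    cat(sprintf("JZS (r = %.3f): BF01 = %.3f, posterior median %.3f, 95%% CrI [%.3f, %.3f]\n",
                x$prior_scale, x$bf01, x$posterior_median,
                x$credible_interval[1], x$credible_interval[2]))
  }
  invisible(x)
}

#' @rdname paired_ttest
#' @param x A `gl_ttest` object.
#' @param ... Unused.
#' @export
tidy.gl_ttest <- function(x, ...) {
  out <- tibble::tibble(t = x$t, df = x$df, p = x$p, d = x$d,
                        conf_low = x$ci[1], conf_high = x$ci[2])
  if (!is.null(x$bf01)) {
    out$bf01 <- x$bf01
    out$posterior <- x$posterior_median
    out$cred_low <- x$credible_interval[1]
    out$cred_high <- x$credible_interval[2]
  }
  out
}

#' @rdname paired_ttest
#' @export
glance.gl_ttest <- function(x, ...) tidy(x, ...)

# orthonormal contrast matrix for a k-level factor (columns span the
# deviations from the grand mean)
orth_contrasts <- function(k) {
  qr.Q(qr(cbind(1, stats::contr.helmert(k))))[, -1, drop = FALSE]
}

rm_effect <- function(Z, data_scale = 1) {
  # Z: n x q orthonormal contrast scores for one within effect. Scores that
  # are pure round-off relative to the input magnitude (an effect that is
  # exactly absent) are snapped to zero so F ratios do not form from noise.
  if (max(abs(Z)) < 1e-10 * (data_scale + 1)) Z[] <- 0
  n <- nrow(Z); q <- ncol(Z)
  m <- colMeans(Z)
  ssh <- n * sum(m^2)
  E <- crossprod(sweep(Z, 2, m))
  sse <- sum(diag(E))
  df1 <- q; df2 <- q * (n - 1)
  # degenerate cells (no effect and/or no error variance) resolve to F = 0
  # rather than 0/0
  Fv <- if (ssh == 0) 0 else (ssh / df1) / (sse / df2)
  eps <- if (sse == 0) 1 else sum(diag(E))^2 / (q * sum(E * E))
  if (q > 1 && sse > 0 && det(E) > 0) {
    # Mauchly's sphericity test on the contrast covariance
    W <- det(E) / (sum(diag(E)) / q)^q
    f <- 1 - (2 * q^2 + q + 2) / (6 * q * (n - 1))
    chi2 <- -(n - 1) * f * log(W)
    mauchly_p <- stats::pchisq(chi2, q * (q + 1) / 2 - 1, lower.tail = FALSE)
  } else {
    mauchly_p <- NA_real_
    if (q == 1) eps <- 1
  }
  tibble::tibble(
    df1 = df1, df2 = df2, F = Fv, p = pf(Fv, df1, df2, lower.tail = FALSE),
    pes = ssh / (ssh + sse), mauchly_p = mauchly_p, gg_epsilon = eps,
    p_gg = pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE))
}

#' Repeated-measures ANOVA with sphericity handling
#'
#' Fully within-subject ANOVA for one or two crossed factors: per effect it
#' reports F, degrees of freedom, p, partial eta squared, Mauchly's
#' sphericity test and the Greenhouse-Geisser epsilon; when Mauchly's test
#' is significant (p < 0.05) for an effect with 3+ levels, the
#' Greenhouse-Geisser-corrected degrees of freedom and p-value are the
#' reported ones. Subjects with incomplete cells are dropped (listwise),
#' and recorded in the result — missing data reduce the error df rather
#' than being filled in.
#'
#' @param data Long-format tibble.
#' @param dv Name of the outcome column.
#' @param subject Name of the subject-identifier column.
#' @param within Names of one or two within-subject factor columns.
#' @return A `gl_anova` with a per-effect tibble (see [tidy()]), the number
#'   of complete subjects and any dropped subject ids.
#' @export
#' @examples
#' set.seed(1)
#' d <- tidyr::expand_grid(subject = 1:12, time = c("t0", "t30", "t24h"),
#'                         drug = c("drug", "placebo"))
#' d$y <- rnorm(nrow(d))
#' rm_anova(d, "y", "subject", c("time", "drug"))
rm_anova <- function(data, dv, subject, within) {
  stopifnot(all(c(dv, subject, within) %in% names(data)),
            length(within) %in% 1:2)
  levs <- lapply(within, function(w) {
    v <- data[[w]]
    if (is.factor(v)) levels(v) else unique(v)
  })
  names(levs) <- within
  cells <- rev(expand.grid(rev(levs), stringsAsFactors = FALSE,
                           KEEP.OUT.ATTRS = FALSE))  # first factor slowest
  names(cells) <- within
  cell_key <- do.call(paste, c(cells, sep = "\r"))
  data_key <- do.call(paste, c(data[within], sep = "\r"))

  dup <- duplicated(data[c(subject, within)])
  if (any(dup)) {
    abort(sprintf("Duplicated subject-cell rows (e.g. subject %s).",
                  data[[subject]][which(dup)[1]]))
  }
  wide <- matrix(NA_real_, nrow = length(unique(data[[subject]])),
                 ncol = nrow(cells))
  subj_ids <- unique(data[[subject]])
  ri <- match(data[[subject]], subj_ids)
  ci <- match(data_key, cell_key)
  if (anyNA(ci)) abort("Rows with factor levels outside the crossed design.")
  wide[cbind(ri, ci)] <- data[[dv]]
  complete <- stats::complete.cases(wide)
  dropped <- subj_ids[!complete]
  wide <- wide[complete, , drop = FALSE]
  if (nrow(wide) < 2) abort("Fewer than 2 complete subjects.")

  k <- vapply(levs, length, integer(1))
  contr <- lapply(k, orth_contrasts)
  unit <- lapply(k, function(kk) matrix(1 / sqrt(kk), kk, 1))
  effect_mats <- if (length(within) == 1) {
    setNames(list(contr[[1]]), within)
  } else {
    setNames(list(
      contr[[1]] %x% unit[[2]],
      unit[[1]] %x% contr[[2]],
      contr[[1]] %x% contr[[2]]
    ), c(within, paste(within, collapse = ":")))
  }
  table <- purrr::imap_dfr(effect_mats, function(M, nm) {
    res <- rm_effect(wide %*% M, data_scale = max(abs(wide)))
    dplyr::bind_cols(tibble::tibble(effect = nm), res)
  })
  table$correction_applied <- !is.na(table$mauchly_p) & table$mauchly_p < 0.05
  table$df1_reported <- ifelse(table$correction_applied,
                               table$df1 * table$gg_epsilon, table$df1)
  table$df2_reported <- ifelse(table$correction_applied,
                               table$df2 * table$gg_epsilon, table$df2)
  table$p_reported <- ifelse(table$correction_applied, table$p_gg, table$p)
  structure(list(table = table, n_subjects = nrow(wide), dropped = dropped,
                 dv = dv, within = within),
            class = "gl_anova")
}

#' @export
print.gl_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA on '%s' (%d complete subjects%s)\n",
              x$dv, x$n_subjects,
              if (length(x$dropped)) paste0("; dropped: ",
                                            paste(x$dropped, collapse = ", "))
              else ""))
  print(as.data.frame(x$table[, c("effect", "df1_reported", "df2_reported",
                                  "F", "p_reported", "pes", "mauchly_p",
                                  "gg_epsilon")]), digits = 4)
  invisible(x)
}

#' @rdname rm_anova
#' @param x A `gl_anova` object.
#' @param ... Unused.
#' @export
tidy.gl_anova <- function(x, ...) x$table

#' @rdname rm_anova
#' @export
glance.gl_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_dropped = length(x$dropped))
}

#' Exact two-sided binomial test
#'
#' Exact two-sided p-value for `k` successes in `n` trials against success
#' probability `p0`. The default (`"minlike"`) convention sums the
#' probability of every outcome no more likely than the observed one (the
#' convention of [stats::binom.test()]); `"doubling"` doubles the smaller
#' tail, capped at 1.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null success probability, in (0, 1).
#' @param method `"minlike"` or `"doubling"`.
#' @return The two-sided p-value.
#' @export
#' @examples
#' binomial_two_sided(17, 29)  # blinding-guess test against chance
binomial_two_sided <- function(k, n, p0 = 0.5,
                               method = c("minlike", "doubling")) {
  method <- arg_match(method)
  assert_scalar_number(k, "k", 0, n)
  assert_scalar_number(n, "n", lower = 1)
  assert_scalar_number(p0, "p0", 1e-12, 1 - 1e-12)
  probs <- stats::dbinom(0:n, n, p0)
  if (method == "minlike") {
    # relative tolerance guards against ties broken by round-off
    min(1, sum(probs[probs <= probs[k + 1] * (1 + 1e-7)]))
  } else {
    lower <- stats::pbinom(k, n, p0)
    upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
    min(1, 2 * min(lower, upper))
  }
}

#' Dose-response regression
#'
#' Least-squares regression of a within-subject outcome difference (drug
#' minus placebo) on weight-adjusted dose, linear (`degree = 1`) or
#' polynomial (`degree = 2`), reporting the fit's r-squared and overall
#' F-test p-value.
#'
#' @param dose Weight-adjusted doses (mg/kg).
#' @param outcome_diff Outcome differences, same length.
#' @param degree Polynomial degree, 1 or 2.
#' @return A one-row tibble: `degree`, `r_squared`, `p_value`, `n`.
#' @export
#' @examples
#' set.seed(1)
#' dose_response(runif(31, 1.5, 3), rnorm(31))
dose_response <- function(dose, outcome_diff, degree = 1) {
  if (!degree %in% 1:2) abort("`degree` must be 1 or 2.")
  keep <- complete.cases(dose, outcome_diff)
  dose <- dose[keep]; outcome_diff <- outcome_diff[keep]
  if (length(dose) <= degree + 1) {
    abort("Too few complete observations for the requested degree.")
  }
  if (sd(outcome_diff) == 0) {
    # constant outcome: no association by construction
    return(tibble::tibble(degree = degree, r_squared = 0, p_value = 1,
                          n = length(dose)))
  }
  fit <- lm(outcome_diff ~ poly(dose, degree))
  # summary.lm warns on an exactly collinear (perfect) fit; that case is
  # legitimate here and reported as r^2 = 1
  s <- suppressWarnings(summary(fit))
  p <- unname(pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                 lower.tail = FALSE))
  tibble::tibble(degree = degree, r_squared = s$r.squared, p_value = p,
                 n = length(dose))
}
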