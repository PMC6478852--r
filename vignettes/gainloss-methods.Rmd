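---
title: "Models and methods behind gainlossr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gainlossr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gainlossr)
```

# The task and what it measures

The GainLoss task is a three-pair probabilistic selection task used to ask
whether a dopaminergic drug affects the *expression* of learned values,
separately from learning and consolidation. Six symbols form three fixed
pairs. In the Gain pair, symbol A pays +1 (a 20p "GAIN") on 80% of
selections and nothing otherwise; symbol B pays +1 on 20%. The Look pair
(C/D) delivers a valueless "LOOK" outcome at the same 80/20 rates. In the
Loss pair, F costs −1 on 80% of selections and E on 20%. Learning runs as a
30-trial practice block plus two blocks of 90 feedback trials (30 per
pair). Expression is then measured on feedback-free *transfer* phases: all
15 pairings of the six symbols, 6 repetitions each (90 trials), given
immediately after learning, 30 minutes later, and 24 hours later — the
last of these after drug or placebo in a double-blinded within-subject
crossover. Because no feedback is given, nothing new can be learned there:
any drug effect on the 24-hour phase is an effect on retrieval/choice, not
on learning.

Optimal-response coding follows the strict order A > B > C > D > E > F.
The only non-trivial case is the Look pair, whose members both have
expected value zero; the 80% LOOK symbol (C) is coded optimal, and Gain
symbols are optimal against Look symbols, Look against Loss. We implement
the coding as this rank order rather than a raw expected-value comparison
precisely so the C-vs-D convention is honoured. The realised outcome on a
trial never enters the coding.

# The two trial-level models

**Dual-learning-rate Q-learning.** Each symbol carries a value $Q$,
initialised at 0 (the value of NOTHING). After feedback $r \in \{-1,0,1\}$
on the chosen symbol,
$$\delta = r - Q, \qquad Q \leftarrow Q + \begin{cases}
\alpha_+ \delta & \delta > 0\\ \alpha_- \delta & \delta \le 0,\end{cases}$$
and a choice between the two displayed symbols is a softmax on their
values with inverse temperature $\beta$. With rewards coded in
$\{-1,0,1\}$ and $\alpha \in [0,1]$, $Q$ provably stays in $[-1,1]$.

**Opponent actor learning (OpAL).** A critic $V$ learns by a delta rule
(rate $\alpha_c$), and two Hebbian actors learn from the same prediction
error with opposite signs: the Go weight $G \leftarrow G + \alpha_G G
\delta$ and the NoGo weight $N \leftarrow N + \alpha_N N (-\delta)$, both
initialised at 1. Choice combines the actors as $\beta_G G - \beta_N N$,
so the two gains separately control how much behaviour expresses
positively versus negatively learned information. Because the actor update
is multiplicative, a single large error with $|\alpha\delta| > 1$ could
flip a weight's sign; we floor $G$ and $N$ at $10^{-6}$. The critic rate
is not one of the model's fitted learning rates; by default it is tied to
$(\alpha_G + \alpha_N)/2$, and can be fixed to a constant instead. The
fitted OpAL parameters are the two actor rates and the four gains.

**Day-1 versus day-2 choice parameters.** Both models carry separate
choice parameters for day-1 feedback trials ($\beta$; $\beta_G, \beta_N$)
and the 24-hour transfer phase ($\beta_{day2}$; day-2 gains). On a
feedback-free phase the values are frozen, so the inverse temperature is
the *only* parameter the phase identifies — which is exactly where a drug
acting on expression would appear. By default the likelihood covers the
day-1 learning trials plus the 24-hour phase; the 0-minute and 30-minute
phases can be included under the day-1 parameters with frozen values
(`include_early_phases = TRUE`), and practice is never modelled. No value
updates ever occur on feedback-free trials, and the models are blind to
left/right screen position.

# Fitting, model comparison, recovery

Per subject-condition, `fit_rl()` minimises the exact sequential negative
log-likelihood by multi-start Nelder-Mead (10 starts by default) on
transformed coordinates: logit for learning rates, scaled logit onto
$(0, 100)$ for inverse temperatures and gains. The bounded temperature
scale keeps likelihoods finite and fits identifiable; the transforms are
bijective on the open parameter space, so reported estimates always
respect bounds. Starts are drawn uniformly on the transformed scale and
the best final value is kept; the optimiser's relative tolerance is far
below the 1e-6 NLL differences we care about. Fits are bit-reproducible
given a seed. Models are compared by the Bayesian Information Criterion
per unit, $BIC = 2\,\mathrm{NLL} + k \ln n$ with $n$ the number of
modelled trials, aggregated across units by the mean (configurable to the
sum); an exact tie is reported as a tie.

`recovery_report()` and the model-recovery checks simulate agents with
known parameters and refit them. These validations are run in an
*informative* regime (`recovery_population()`): day-1 temperatures around
4 so choices track values, wide learning-rate dispersion so agents are
rankable, and for OpAL clearly separated Go/NoGo gains and actor rates so
its behaviour is not mimicked by the simpler model. This choice is
deliberate and worth stating plainly: at the behavioural cohort's own
near-chance day-1 temperature, per-subject learning rates are only weakly
identified at 180 learning trials (rank correlations of roughly 0.1-0.45
in our experiments). Passing recovery in the informative regime shows the
estimator works where the data carry signal; it does not license strong
interpretation of individual learning rates estimated from near-chance
behaviour.

# The statistical battery

*Paired t-tests* report Cohen's $d = t/\sqrt{n}$ for the within-subject
design and the 95% CI of the mean difference. Identical paired vectors are
a degenerate input (zero-variance differences) and are refused rather than
reported as $t = 0$.

*Bayesian companion tests* use the JZS default: a Cauchy prior of width
$r = 0.707$ on the standardised effect. The Bayes factor is computed by
adaptive quadrature over the inverse-gamma mixing variable of the classic
representation (relative tolerance 1e-8), reported in the null-favouring
orientation $BF_{01} = 1/BF_{10}$. The posterior of the effect is computed
on a 10,001-point grid over $[-6, 6]$ against the noncentral-$t$
likelihood and summarised by its median and central 95% interval; the
cumulative sum uses a midpoint rule so quantiles are unbiased on
symmetric densities (grid-halving changes the median by well under
1e-4). An independent Monte-Carlo marginal-likelihood oracle checks the
quadrature in the test suite. The prior width is exposed
(`--bf-prior-scale`, `prior_scale`) for robustness checks.

*Repeated-measures ANOVA* (`rm_anova()`, one or two within factors) is
computed from orthonormal within-subject contrasts, which yields in one
pass the $F$ ratio, partial $\eta^2$, the Greenhouse-Geisser
$\hat\varepsilon$ and Mauchly's sphericity test. We compute these directly
because the base `anova.mlm()` machinery exposes the corrected p-values
but not $\varepsilon$ or the sums of squares as numbers; the test suite
cross-checks every statistic against `anova.mlm(test = "Spherical")` and
`mauchly.test()`. When Mauchly's test is significant ($p < 0.05$) for an
effect with three or more levels, the Greenhouse-Geisser-corrected
degrees of freedom and p-value are the reported ones; a two-level factor
has $\varepsilon = 1$ and needs no correction. Subjects with incomplete
cells are dropped listwise and named in the result — with 30 complete
subjects in a 3 (time) × 2 (drug) design the error dfs are (2, 58),
(1, 29), (2, 58). Contrast scores that are pure round-off relative to the
data scale are snapped to zero so an exactly absent effect reports
$F = 0$ rather than a ratio of noise.

*Exact binomial tests* implement the "minlike" convention (sum of all
outcome probabilities no larger than the observed one — the convention of
`binom.test()`) with tail-doubling available by flag. The two agree for
balanced cases; e.g. 17 correct guesses out of 29 at chance gives
$p \approx 0.458$ under both. Values printed by point-and-click packages
can differ when a mid-p or normal-approximation convention is in play, so
the convention is always part of the report.

*Dose-response regressions* regress the within-subject outcome difference
on weight-adjusted dose (dose in mg divided by body weight in kg), linear
or quadratic, reporting $r^2$ and the overall F-test p-value.

No multiplicity correction is applied across the report grids — the
reporting convention the pipeline emulates is per-test — and the generated
report says so in a footnote.

# The synthetic cohort

`generate_cohort()` produces the full crossover structure the analysis
assumes: 31 subjects by default, each completing both conditions with
distinct stimulus sets, condition order counterbalanced, practice + two
learning blocks + three transfer phases per condition, subject metadata
(body weight ~ N(75, 12²) kg truncated at 40, age ~ N(71.2, 7.4²)
truncated at 65, MoCA ~ round(N(26.2, 3.1²)) capped at 30, 150 mg dose),
and ground-truth parameters kept in a separate table from the observed
data. Agent parameters are drawn per subject on the transformed scale
(logit for rates, log for temperatures); the drug condition applies a
configurable additive shift to the day-2 choice parameter(s) on that
scale, so a zero effect gives exactly coupled null conditions and a shift
of 1 multiplies the day-2 temperature by $e$ within subject. Missingness,
when enabled, removes whole choice phases (absent, never zero-filled),
which propagates to listwise-deleted statistics downstream. All
randomness descends from one master seed through named substreams
(`substream_seed()`), so every stage is independently reproducible.

The default population hyperparameters are calibrated to the qualitative
behavioural pattern the analysis is designed around — near-chance learning
accuracy with clearly above-chance transfer: $\alpha_+ \sim
\text{logit-N}(\text{logit}(0.25), 0.7^2)$, $\alpha_- \sim
\text{logit-N}(\text{logit}(0.18), 0.7^2)$, $\beta \sim
\text{log-N}(\log 0.7, 0.4^2)$, $\beta_{day2} \sim \text{log-N}(\log 1.8,
0.4^2)$, giving about 56% learning accuracy and about 72% 24-hour
accuracy in our runs. These are configuration values, not empirical
claims.

What the generator deliberately does **not** emulate: reaction times and
response deadlines, choice perseveration or other sequential dependencies
beyond the models themselves, questionnaire item responses, physiological
measures, and any drug mechanism other than a day-2 choice-parameter
shift (an OpAL-style asymmetric shift of the day-2 gains is available as
an alternative effect locus). Passing the pipeline's tests on this cohort
therefore shows that the machinery is correct and calibrated under the
stated generative assumptions — not that real data satisfy those
assumptions.

# Numerical choices

- Softmax probabilities are computed with max-subtraction and floored at
  the smallest positive double, so they are strictly positive and
  normalise to 1 within 1e-12 even at extreme strengths.
- Outcome sampling is i.i.d. Bernoulli per trial by default; an exact-mix
  mode shuffles a fixed per-symbol, per-block outcome list whose
  composition matches the contingency as closely as the count allows
  (exact at multiples of 5). Left/right position is uniform at random and
  has no effect on contingencies.
- The likelihood inner loops (and learning-phase simulation) are in C++
  via Rcpp; the test suite holds them to 1e-10 agreement against a plain-R
  brute-force unrolling on short sequences and 1e-8 on study-length ones.
- Optimiser: Nelder-Mead, 2000 iteration cap, relative tolerance 1e-10 on
  the objective; temperatures bounded to (0, 100).
- Validation problem sizes (chosen as the package's standard desk-scale
  settings): parameter recovery pools 2 cohorts of 31 agents at 180
  learning + 90 transfer trials; model recovery uses 20 replicates per
  generating model with 6-agent cohorts; the type-I calibration runs 500
  null cohorts of the full 31 × 2 structure and checks the paired 24-hour
  accuracy test rejects at 5% within binomial error.

# Known limitations

- Maximum-likelihood point estimates per subject, not hierarchical
  estimation; shrinkage-based designs would recover weakly identified
  parameters better at these trial counts.
- The models deliberately omit perseveration kernels, forgetting, and
  Pavlovian biases; misfit from such processes loads onto the temperature
  parameters.
- The Bayesian repeated-measures ANOVA family (inclusion Bayes factors)
  is out of scope; Bayesian inference here is limited to the JZS paired
  tests.
- Posterior credible intervals depend mildly on grid convention in their
  third decimal; the package's grid is fixed and documented above.

```{r example, eval = FALSE}
# a complete run, from synthetic cohort to report bundle
rep <- run_pipeline("gl-report", seed = 1,
                    models = c("qlearning", "opal"), n_starts = 10)
rep$comparison
tidy(rep$frank)
```
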