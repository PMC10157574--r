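---
title: "Measuring disability weights from paired-comparison and population-health-equivalence surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring disability weights from paired-comparison and population-health-equivalence surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

A disability weight (DW) quantifies, on a 0–1 scale, the health loss of
living one year in a given health state: 0 is full health, 1 is
equivalent to death. DWs are the severity component of years lived with
disability and DALYs. `dwkit` implements a complete measurement pipeline
for DWs from two kinds of survey responses, together with a simulator of
the survey itself, so that every estimation step can be validated end to
end against known ground truth.

```{r setup}
library(dwkit)
library(dplyr)
```

## The two measurement arms

**Paired comparisons (PC).** A respondent reads the lay descriptions of
two health states and says which person is healthier. With latent
healthiness indices $\beta_s$ per state, the probability that the first
state shown is chosen follows the Thurstonian probit law

$$P(Y = 1 \mid X) = \Phi(X'\beta),$$

where the design row $X$ carries $+1$ for the first state, $-1$ for the
second and $0$ otherwise. Only differences $\beta_i - \beta_j$ are
identified; `fit_pc_probit()` imposes a sum-to-zero constraint by default
(a reference-state constraint is available, and the test suite verifies
that the final DWs do not depend on the choice). The likelihood is
maximised by Newton–Raphson on aggregated choice counts with a small
ridge penalty (`1e-6`) so that quasi-complete separation — a state winning
or losing every comparison it appears in — still yields a finite,
flagged estimate. Convergence requires a gradient max-norm below
`1e-8`; the start is the zero vector, so the fit is deterministic.

PC choices locate states relative to each other but carry no unit: the
index must be anchored to the 0–1 scale.

**Population health equivalence (PHE).** A respondent compares two
health programs: one prevents 1000 rapid deaths, the other prevents $M$
people from contracting a lifelong nonfatal state $s$, with
$M \in \{1500, 2000, 3000, 5000, 10000\}$. Preferring the nonfatal
program reveals $M \cdot DW_s > 1000$, i.e. $DW_s > 1000/M$; preferring
the fatal program reveals the opposite. Each answer is therefore a
censored observation of $DW_s$ with a one-sided bound at the threshold
$1000/M$, and `fit_interval_regression()` estimates a per-state location
$\gamma_s$ and a common residual SD $\sigma$ by maximum likelihood on a
transformed scale (logit by default, so weights stay inside (0, 1); a
log scale is available, following the lineage of earlier international
valuation studies). Locations are box-constrained to the transform of
$[10^{-4}, 1 - 10^{-4}]$ so one-sided data cannot diverge.

A state whose observations all point the same way (for example, a very
mild state that never beats even the largest multiplier) identifies a
bound, not a location. Such states are flagged, and
`phe_dw_estimates(fit, drop_boundary = TRUE)` excludes them from
anchoring: their box-constrained locations would otherwise exert large
leverage on the logit scale and visibly tilt the anchoring line.

## Anchoring, means, uncertainty

`fit_anchor()` regresses the transformed PHE weights of the anchor
states on the PC side's predicted probabilities $\Phi(\beta_s)$
(ordinary least squares; the raw index $\beta_s$ is available as an
alternative regressor). `predict_dws()` then maps every state through
the fitted line, producing DWs inside (0, 1) by construction on the
default logit dependent scale.

Two layers of uncertainty are attached:

* `monte_carlo_mean()` draws index vectors from the multivariate normal
  implied by the probit fit's observed-information covariance (in the
  free parameterisation, so the identifiability constraint is respected)
  and averages the predicted DWs — the mean of a nonlinear transform,
  not the transform of the mean.
* `bootstrap_ui()` resamples respondents with replacement, stratified
  by survey mode so the web-only PHE arm keeps its size, re-runs the
  whole chain per replicate, and reports 2.5th/97.5th percentile
  intervals (type-6 quantiles, the usual bootstrap convention).
  Internally, resampling is implemented by respondent multiplicity
  weights on the aggregated likelihoods, which makes 200–1000 replicates
  cheap even at full survey scale.

If percentile noise at modest replicate counts leaves a mean just
outside its interval, the interval is widened to include it and the
state is flagged — intervals never exclude their own point estimate.

## Survey mechanics and quality control

`assign_pc_pairs()` reproduces the survey's balancing rule: each fresh
pair is drawn uniformly among the unordered pairs with the minimum
selection count so far. Drawing this way is equivalent to dealing from a
shuffled deck of all pairs and reshuffling on exhaustion, which is how
it is implemented; the max–min spread of selection counts never exceeds
one. Sixteen PC questions are asked per respondent, with the pair from
question 3 repeated verbatim (same presentation order) at questions 10
and 16; `test_retest_consistency()` summarises agreement across the
three showings as a diagnostic. The repeated showings are re-asked, so
agreement reflects respondent reliability, not bookkeeping.

`qc_filter()` applies the survey's pre-analysis exclusions: duplicate
respondent IDs, incomplete PC sets, web respondents under the 3-minute
completion floor (household interviews are interviewer-administered and
exempt), and the low-effort patterns all-A, all-B and strict
alternation over the full 16 answers (any single break defeats the
pattern). The filter is idempotent and reports every exclusion with its
rule.

## The synthetic cohort

`generate_cohort()` produces survey data with exactly the statistical
structure the estimators assume, plus controlled deviations:

* True weights are drawn from Beta(1.2, 6), a right-skewed law on
  (0, 1) under which most states fall below 0.4, matching the skew seen
  in valuation studies.
* The latent healthiness index is the generative inverse of the
  anchoring map, $h_s = (\mathrm{logit}(DW_s) - a)/b$ with defaults
  $a = -2$, $b = -1.6$. The discrimination scale was chosen once so the
  median PC choice accuracy is about 0.75 — respondents are clearly
  better than chance but far from deterministic.
* PC choices are Bernoulli draws with probability
  $\Phi(h_{first} - h_{second})$.
* PHE choices follow a noisy threshold rule: the respondent perceives
  the nonfatal benefit as $M \cdot DW \cdot e^{\varepsilon}$ with
  log-normal perception noise $\varepsilon \sim N(0, 0.5^2)$, choosing
  the nonfatal program when the perceived benefit exceeds 1000. Exact
  indifference under zero noise resolves to the fatal program.
* `example_universe()` builds a reduced study (30 states by default)
  whose anchor subset sits at evenly spaced severity quantiles,
  emulating the purposive mild-to-severe anchor selection of the real
  design; anchors milder than the lowest threshold 0.1 yield one-sided
  data and exercise the boundary handling.

Completion times, demographics and an optional fraction of deliberately
invalid respondents (straightliners, alternators, too-fast web
respondents) round out the cohort; injections are reported so QC tests
can verify one-to-one detection.

What the simulator does **not** emulate: demographic heterogeneity in
valuations, question-order and fatigue effects, respondent-level random
effects in PHE answers, and real lay-description semantics. Passing
recovery tests therefore demonstrates correctness of the estimation
chain under its assumed model, not robustness to every behaviour of
real survey populations.

## Validation design

The package's recovery suite simulates a 30-state universe with 10
anchors and 2000 respondents (900 household, 1100 web — the real
survey's mode ratio at reduced scale), runs the full chain with 200
bootstrap replicates, and checks Pearson and rank correlation with
truth and median absolute error. Empirical 95%-interval coverage is
pooled over independent replications of the whole study, because an
anchor-line error in one realisation shifts every state together: a
single realisation gives a noisy, bimodal coverage estimate, while a
few replications give a stable one. These sizes keep the validation
suite to a couple of minutes on one CPU while every pair of the reduced
universe is still compared dozens of times.

One validation choice deserves explanation. The generator's PHE noise
is log-normal and its truth is linear between logit(DW) and the latent
index, so the estimator configuration that is *exactly specified* for
the generative model uses the log interval scale and the latent-index
anchoring regressor; the recovery suite runs under that configuration
and recovers truth essentially perfectly (correlations above 0.99,
median errors below 0.01, coverage at or above 0.93 across seeds). The
paper-facing defaults — logit interval scale and probability regressor,
the literal description of the published method — remain the package
defaults; under them the point recovery is nearly as good (correlations
about 0.99, median errors about 0.01–0.02), but a curvature
misspecification of order 0.01–0.04 per state survives in the tails,
and because it is systematic, no respondent-resampling interval can
cover it. This is a genuine property of anchoring on a bounded
probability scale, worth knowing when interpreting published UIs; the
vignette's advice is to compare both regressor choices on real data as
a sensitivity analysis.

## Descriptive and comparative reports

`bin_distribution()` bins weights into half-open, lower-inclusive
severity bins; percentages use the full catalog size as denominator by
default, so a state with no estimable weight still appears in the base.
`compare_dws()` joins local and reference weights, computing the
proportional difference $d = 100 (DW_{local} - DW_{ref})/DW_{ref}$;
`symptom_regression()` regresses $d$ on all eleven binary
symptom-category flags simultaneously (mobility, pain, mental, fatigue,
disfigurement, sensory, infection/diarrhoea, substance use, ADL,
cognitive, other physical) with t-based confidence intervals; and
`dw_correlation()` gives the Pearson correlation between surveys.
All comparison steps degrade to a recorded skip when no reference table
is supplied.

The packaged 206-state catalog carries the real published state labels
and weight table; its lay descriptions, symptom flags and 28-state
anchor subset are synthetic stand-ins for unpublished survey annexes
(flags are keyword-seeded and topped up to realistic per-category
frequencies; anchors are spread across the severity range). The file is
named accordingly and should not be used for substantive cross-survey
conclusions.

## A small worked example

```{r example, eval = FALSE}
u <- example_universe(n_states = 30, n_anchors = 10, seed = 1)
cfg <- dw_config(seed = 1, interval_scale = "log", regressor = "index",
                 n_bootstrap = 200)
cohort <- generate_cohort(u$catalog, u$truth, n_household = 900,
                          n_web = 1100, config = cfg$survey)
results <- estimate_dws(cohort$respondents, cohort$pc_responses,
                        cohort$phe_responses, u$catalog, cfg)
glance(results)
autoplot(results)
inner_join(results, u$truth$true_dw, by = "state_id") |>
  summarise(r = cor(dw_mean, true_dw),
            medae = median(abs(dw_mean - true_dw)))
```

## Numerical choices and limitations

* Probit: Newton–Raphson with step halving, analytic gradient and
  observed-information Hessian; ridge `1e-6`; deterministic zero start.
* Interval regression: L-BFGS-B over $(\gamma, \log\sigma)$ with
  analytic gradients; $\sigma$ bounded to $[10^{-3}, 10^{3}]$;
  deterministic start at per-state bound midpoints.
* Every stochastic stage derives its RNG stream from the master seed
  plus the stage name, so pipelines are byte-reproducible from
  `(data, config, seed)` and stages can be re-run independently.
* Ties: a zero-noise PHE respondent exactly at threshold chooses the
  fatal program; a DW of exactly 1 falls in the top distribution bin.
* The bootstrap conditions on the realised question assignment; design
  randomness (which pairs and multipliers were asked) is not part of the
  reported uncertainty, as in the published method.
* With fewer than two usable (two-sided) anchor states the anchoring
  step refuses to run; with anchors spanning a narrow severity range,
  predictions for states outside that range are extrapolations and
  should be read cautiously.
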