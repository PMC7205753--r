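---
title: "Surrogate-guided adaptive seamless designs: models, decisions, and operating characteristics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-guided adaptive seamless designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surradapt)
```

## The design problem

A two-stage seamless phase 2/3 trial investigates several doses against a
control on a time-to-event primary endpoint that takes years to observe —
here, time to confirmed disability *improvement*, so that **shorter times
and more events mean benefit**. Because primary-endpoint information is
scarce at the interim, dose selection is driven by a continuous early
surrogate score (on the scale $[-4, 4]$, observed after 26 weeks of
exposure). The package answers the design-stage questions: how often does
the interim rule pick the right dose, what are the overall and conditional
power, how often does the trial stop wrongly, and what sample size does the
adaptive design actually spend?

## The surrogate/primary linkage model

The correlation between surrogate $X$ and event time $T$ is not assumed as
a single number. It is *modelled* from historical subject-level data with a
log-normal accelerated-failure-time regression

$$\log T = a + bX + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2),$$

fitted in a Bayesian way: flat improper priors on $(a, b)$ and a
Gamma$(0.001, 0.001)$ prior on the precision $1/\sigma^2$.
`fit_lognormal_model()` is a Gibbs sampler with exact conjugate updates for
the coefficients and the precision; right-censored records are handled by
truncated-normal augmentation of the latent log-time, which keeps every
conditional in closed form and needs no tuning. A single chain with 1000
burn-in iterations and 5000 retained draws is the default; with conjugate
updates the draws are nearly uncorrelated and split-half means agree within
Monte-Carlo error at these sizes.

Two genuinely open choices are worth recording:

* **Where the Gamma prior sits.** Placing Gamma$(0.001,0.001)$ on the
  precision is the conjugate convention in Bayesian survival practice and
  is the default. A direct Gamma prior on $\sigma$ itself is available via
  `prior_spec(prior_on = "sigma")` (a Metropolis step on $\log\sigma$);
  with noninformative settings the two are indistinguishable in the
  posterior means at realistic sample sizes.
* **The reference historical fixture.** The package ships no subject-level
  historical data; `generate_historical_data()` builds synthetic datasets
  from the model itself. The reference fixture uses $n = 500$ complete
  records with $X \sim \mathrm{Uniform}(-4, 4)$ and parameters
  $(a, b, \sigma) = (0.16, -1.37, 1.53)$ — a realistic size and surrogate
  spread for a pooled placebo-arm cohort, and the parameter values used
  throughout as the reference linkage. Fitting the model to such a fixture
  reproduces those values up to sampling noise.

Before the surrogate is trusted for decision-making,
`check_slope_validity()` requires the 95% credible interval of $b$ to
exclude zero (the interval is treated as closed: an endpoint at exactly
zero fails). The downstream inversion divides by $b$, so fits with
$|b| < 10^{-6}$ are rejected outright.

## Simulating a trial

`simulate_trial()` builds one trial per call:

* **Event times.** Each arm's 3-year event rate $p$ is converted to an
  exponential hazard $\lambda = -\log(1-p)/156$ per week
  (`event_rate_to_hazard()`); latent event times are exponential.
* **Surrogates.** The linkage is inverted:
  $X = (\log T - a)/b + \varepsilon'$ with
  $\varepsilon' = -\varepsilon/b \sim N(0, (\sigma/|b|)^2)$. The *latent*
  event time is used — the model links the surrogate to the event process
  itself, and censoring is an observation artefact. No direct treatment
  effect on the surrogate is assumed; it is induced entirely by the
  event-rate differences.
* **Enrollment.** Deterministic, evenly spaced arrivals at a constant rate
  (default $4 \times 20 / 26$ per week), permuted-block randomized over all
  open arms. The IA fires when 20 subjects per arm carry 26 weeks of
  exposure; at the defaults that is calendar week
  $26 + 80/(80/26) = 52$, with 160 subjects on study.
* **Dropout.** Exponential with $P(\text{dropout} \le 156) = 0.05$,
  independent of the event time, censoring the primary endpoint only. The
  surrogate is assumed observed for everyone reaching 26 weeks (whether
  dropout should also truncate the surrogate window is genuinely
  unspecified in this setting; the engine takes the permissive reading).
* **The interim rule.** Let $\bar X_{\max}$ be the best active-arm
  surrogate mean among the 20-per-arm mature cohorts and $\bar X_0$ the
  control mean. The best arm continues iff
  $\bar X_{\max} - \bar X_0 \ge \Delta$; otherwise the trial stops for
  futility. Exact ties are broken uniformly at random.
* **Stage 2.** Enrollment never pauses, so each continuing arm's stage-2
  quota of 124 *includes* its pre-IA enrollees with immature surrogates
  (20 per continuing arm at the defaults). This is the accounting under
  which $4 \times 20 + 2 \times 124 + 40 = 368$ preplanned subjects, of
  which the 40 immature subjects of the two dropped arms never enter the
  analysis. Each analysed subject is followed exactly 156 weeks.

## The final analysis

Each active-vs-control comparison contributes a log-rank statistic
$(U, V)$ (observed-minus-expected events with hypergeometric variance;
positive $U$ favours the active arm). Stage-1 statistics
$Z_1 = U_1/\sqrt{V_1}$ use the mature interim cohorts censored at the IA
calendar week; the stage-2 increment
$Z_2 = (U_2 - U_1)/\sqrt{V_2 - V_1}$ uses the full data of the continuing
arms and is asymptotically independent of $Z_1$. Zero-information stages
are mapped to $Z = 0$ (a degenerate increment with $V_2 - V_1 \le
10^{-12}$ would otherwise divide by zero and corresponds to a
no-information p-value of 0.5).

The closed testing procedure enumerates all non-empty intersections of the
$k$ elementary hypotheses. Within stage 1, multiplicity is handled by
Dunnett's many-to-one adjustment (equicorrelation $1/2$ at equal
allocation), computed by deterministic multivariate-normal quadrature to
absolute accuracy better than $10^{-6}$. The stage-2 p-value of an
intersection is the unadjusted one-sided p of the selected arm when the
intersection contains it, and 1 otherwise. Stages are combined with the
weighted inverse-normal function

$$C(p_1, p_2) = 1 - \Phi\!\left[w_1 \Phi^{-1}(1-p_1) +
w_2 \Phi^{-1}(1-p_2)\right], \qquad w_1^2 + w_2^2 = 1,$$

and $H_i$ is rejected iff every intersection containing it falls below
$\alpha = 0.025$ one-sided. The information-fraction weights must satisfy
the quadratic constraint, so the defaults are
$w_1 = \sqrt{n_1/(n_1+n_2)}$, $w_2 = \sqrt{n_2/(n_1+n_2)}$ with
per-comparison analysed counts $n_1 = 40$, $n_2 = 248$ — with a single
selected arm the per-comparison and total-stage fractions coincide, and
the square root is forced by the constraint. p-values from Z statistics
are clipped to $[10^{-15}, 1-10^{-15}]$.

A structural consequence of single-arm selection: only the selected arm's
hypothesis can ever be rejected (every other hypothesis has a singleton
intersection whose stage-2 p-value is 1). The Monte-Carlo engine exploits
this for speed; tests verify its equivalence with the full enumeration. A
trial stopped for futility performs no final test.

## Operating characteristics

`run_oc()` replicates the pipeline (default 5000 replicates; binomial
Monte-Carlo SE at most 0.7 percentage points) either at fixed linkage
parameters or consuming one posterior draw per replicate. Internally each
replicate is simulated once with the best arm always carried forward and
then *re-decided* at the requested threshold(s): given continuation,
neither the selection nor the stage-2 data depend on $\Delta$, so a single
set of realizations serves `threshold_sweep()`, the familywise-error scan,
and the false-stopping ("flip-flop") probability — the joint probability
that a trial stops at the IA *and* its counterfactual continuation would
have rejected. The joint (not stopped-conditional) convention is the one
consistent in magnitude with a false-stopping risk smaller than the
futility probability itself. Common random numbers also make carry-forward
monotone in $\Delta$ replicate-wise and power monotone in the stage-2 size
during `find_stage2_n()` bisection.

`traditional_design_n()` gives the non-adaptive comparator: all arms
enrolled to a common size, followed 156 weeks, tested once with Dunnett's
adjustment; the smallest per-arm n with simulated power at the target is
found by bisection. Near 90% power the curve is flat (about 0.3–0.4
percentage points per subject), so repeated searches at 5000 replicates
scatter over roughly $\pm 2$ subjects; this is inherent Monte-Carlo
granularity, not search error.

Reported identities hold exactly on the realized replicates:
carry-forward + futility = 1, selection probabilities sum to
carry-forward, overall power = conditional power × carry-forward, and
expected N = carry-forward × 368 + futility × 160 at the defaults.

## What the generator does and does not emulate

The synthetic trials embody the stated design conditions: exponential
event and dropout laws, a homogeneous surrogate/primary linkage across
arms, deterministic constant enrollment, and a surrogate observed exactly
at maturation. Real trials violate all four in ways this engine does not
model: non-proportional hazards or cure fractions, arm-specific
surrogate biology, ramp-up and seasonal enrollment, and missed or delayed
surrogate assessments. Passing operating-characteristic checks therefore
validates the design machinery under its assumptions — it does not certify
the surrogate's clinical validity, which must come from the historical
fit and its credible-interval check (and ultimately from domain
judgement).

## Numerical choices and limitations

* Problem sizes: the shipped analyses use 5000 replicates for operating
  characteristics and 4-arm designs of at most 368 subjects; unit tests
  use smaller replicate counts sized so that 3-standard-error bands keep
  them stable.
* Dunnett probabilities use deterministic algorithms (bivariate/trivariate
  quadrature up to dimension 3, lattice quadrature to dimension 5);
  results are bitwise reproducible for a fixed master seed, which derives
  one RNG seed per replicate.
* Selection with `n_select > 1` is reserved in the configuration but not
  implemented; the closure machinery itself supports only a single
  selected arm's stage-2 increment.
* Only exponential event laws are provided. The linkage model's error is
  normal on the log scale; Weibull or log-logistic variants would change
  both the fit conditionals and the inversion and are deliberately out of
  scope.
* Stage-1 p-values at the IA use only the mature cohorts: immature
  pre-IA enrollees carry no 26-week exposure at the cut and their
  primary-endpoint information enters through the stage-2 increment.
  Post-IA follow-up of dropped-arm subjects is never used in the test
  statistics, matching the analysis-set accounting above.

## A worked miniature

```{r, eval = FALSE}
hd <- generate_historical_data(500, a = 0.16, b = -1.37, sigma = 1.53,
                               seed = 1)
fit <- fit_lognormal_model(hd, seed = 1)
summarize_posterior(fit)

design <- design_config()   # Scenario-1 rates, delta = 0.3, 124/arm stage 2
run_oc(design, oc_config(n_replicates = 1000, master_seed = 1))
```
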