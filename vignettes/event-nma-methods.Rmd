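---
title: "Models and methods: network meta-analysis of event risks and rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: network meta-analysis of event risks and rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Randomised trials of treatments that prevent recurrent adverse events — the
motivating case is severe hypoglycaemia under different basal insulin
regimens in type 1 diabetes — report the outcome in two incompatible
summaries. Some report the *risk*: the number of patients with at least one
event out of those randomised, over the trial's follow-up. Others report the
*rate*: the total number of events over the total person-years of exposure,
which counts repeat events in the same patient. A network meta-analysis (NMA)
that wants to use all the evidence has to put both on a common scale, and a
health-economic model downstream needs an *absolute* event probability, which
turns out to be far more sensitive to the modelling choice than the relative
effects are.

`eventnma` implements the four arm-level Bayesian NMA likelihoods relevant to
this situation, the single-arm baseline meta-analyses that anchor absolute
predictions, deviance-based model criticism, and the propagation of
probabilities into expected costs and disutilities. It also ships a
simulator that generates coherent risk- and rate-format data from a single
latent event process with known ground truth, which is what the test suite
exercises.

## Relative-effect models

All four models share the arm-level linear predictor structure used
throughout contrast-based NMA. Study $i$ has a baseline parameter $\mu_i$
(an unrelated nuisance parameter) and each non-baseline arm $k$ a
trial-specific effect $\delta_{ik}$, with $\delta_{i1} = 0$:

* **logit**: $r_{ik} \sim \mathrm{Bin}(n_{ik}, p_{ik})$,
  $\mathrm{logit}(p_{ik}) = \mu_i + \delta_{ik}$. Relative effects are log
  odds ratios. Follow-up time is deliberately ignored: the model treats the
  chance of a first event as unrelated to how long patients were observed,
  so the pooled baseline reflects the *average* follow-up of the
  contributing trials, not any fixed horizon.
* **cloglog**: $\mathrm{cloglog}(p_{ik}) = \log T_i + \mu_i + \delta_{ik}$,
  with $T_i$ the follow-up in years entering as a log-time offset. Under a
  constant event hazard this makes $\mu_i$ and $\delta_{ik}$ log hazards and
  log hazard ratios per year, estimable from risk summaries alone.
* **Poisson**: $y_{ik} \sim \mathrm{Pois}(E_{ik}\lambda_{ik})$,
  $\log \lambda_{ik} = \mu_i + \delta_{ik}$, for rate data over person-years
  $E_{ik}$. Also a log-hazard scale, but informed by repeat events.
* **shared-parameter**: risk-only studies contribute through the cloglog
  likelihood and studies with rate records through the Poisson likelihood —
  when a study reports both formats its rate records are preferred — with a
  *common* vector of basic parameters $d$ (and common heterogeneity SD).
  This is coherent because both likelihoods estimate log hazard ratios,
  provided events behave like a homogeneous Poisson process: the hazard is
  constant over follow-up and does not change after the first event.

Under **fixed effects** $\delta_{ik} = d_{t_{ik}} - d_{t_{i1}}$; under
**random effects** $\delta_{ik} \sim N(d_{t_{ik}} - d_{t_{i1}}, \sigma^2)$
with the conditional sequential construction for trials with more than two
arms, which induces the $\sigma^2/2$ covariance between contrasts sharing an
arm. Under **consistency** all contrasts derive from the basic parameters
$d_k$ (relative to treatment 1, $d_1 = 0$); the **inconsistency**
(unrelated-mean-effects) structure instead gives every observed comparison
its own mean parameter, and comparing the two fits probes whether direct and
indirect evidence disagree.

Sampling is MCMC via JAGS. Default priors are vague and configurable:
$d_k, \mu_i \sim N(0, 100^2)$ on the linear-predictor scale and
$\sigma \sim U(0, 2)$ — an upper bound of 2 on a log-hazard or log-odds
scale is far beyond plausible between-trial variation for this outcome.
Defaults are 4 chains of 2000 retained draws after 1000 discarded; the fits
report split-$\hat R$ and effective sample size for every basic parameter
and attach a warning when any $\hat R$ exceeds 1.05. Identical seeds give
identical draws (each chain's RNG is seeded as `seed + chain - 1`).

## Baseline meta-analysis and absolute outcomes

Relative effects alone do not feed an economic model; one needs the absolute
probability of an event on the reference treatment. `fit_baseline` pools the
reference arms of the contributing trials on the scale matching the NMA:
logit (probability over the trials' own follow-ups), cloglog (log hazard,
probability at a chosen horizon), or log-rate (Poisson, events per
person-year). Random effects place $\theta_i \sim N(m, sd_m^2)$; the
reported baseline uses the posterior of the summary mean $m$, not the wider
predictive distribution for a new study (available via `predictive = TRUE`),
because a decision model usually wants the expected population baseline.

`combine_absolute` then applies each relative-effect draw to each baseline
draw: $\mathrm{logit}(p_k) = \mathrm{logit}(p_1) + d_k$ on the odds scale,
and $\mathrm{cloglog}(p_k) = \mathrm{cloglog}(p_1) + d_k$ — equivalently
$p_k = 1 - \exp(-\exp(m + d_k)\,t)$ — on the hazard scales, using the
constant-rate transform $p = 1 - \exp(-rt)$. The baseline and NMA posteriors
come from separate models, so draws are paired independently after
resampling to a common length under a fixed seed; there is no joint
posterior to preserve.

Rankings are computed within each draw (fewest events ranks first; ties
broken by treatment code so results are deterministic), and costs and
disutilities are draw-wise linear transforms: cost per event times the
probability of at least one event, and the utility decrement times the same
probability. Costing the *probability* rather than the expected *number* of
events understates the burden when repeat events occur; that convention is
kept deliberately because it is how per-event costs are usually attached to
risk-based probabilities, and an events-based alternative
($c \cdot r \cdot t$) is available via `expected_cost(..., events_based =
TRUE)` but off by default.

Three facts about the baseline probabilities are worth internalising:

1. the logit baseline refers to the trials' average follow-up — if that is
   under a year it will sit *below* a one-year probability;
2. the cloglog baseline at one year exceeds the logit one for the same data
   whenever mean follow-up is under a year;
3. the Poisson baseline exceeds both on real data where repeat events
   cluster in high-risk patients, because the event rate then exceeds the
   first-event hazard.

Point 3 is a property of *data*, not of the models: under an exactly
homogeneous Poisson process the first-event hazard equals the event rate and
the cloglog and Poisson one-year baselines coincide in expectation. The
simulator below generates exactly that process, so in simulation the
cloglog/Poisson gap is a near-tie decided by sampling noise, and tests of
the full three-way ordering sit on a knife edge for the second inequality.
This is a known, deliberate limitation of the simulator, not of the models.

## Model criticism

Fit is judged by the posterior mean of the summed saturated residual
deviance $\bar D$ (about one per data point in a well-fitting model), the
effective number of parameters $p_D = \bar D - D(\bar{\text{fit}})$ computed
by the classic plug-in at the posterior mean of the fitted values (the
WinBUGS convention; not the half-variance form), and
$\mathrm{DIC} = \bar D + p_D$. Zero cells use the $0 \log 0 = 0$ convention.
`compare_models` selects the lowest DIC but keeps the simpler model when the
difference is under 3 — differences that small are not meaningful — and
flags potential inconsistency when an unrelated-mean-effects fit attains the
smallest $\bar D$ or DIC.

## The simulator

`simulate_network` draws, per study: a baseline log rate
$\mu_i \sim N(\log 0.38, 0.5^2)$ by default; trial-specific log hazard
ratios around the true $d$ with SD $\sigma$ (split into a shared study term
and an arm term so multi-arm contrasts have the correct $\sigma^2/2$
covariance); a follow-up $T_i$; and per-patient event counts
$\mathrm{Pois}(\lambda_{ik} T_i)$. The risk summary counts patients with
$\geq 1$ event and the rate summary sums all events over $E = nT$ — both
from the *same* latent counts, so for studies reporting both formats
$y \geq r$ arm-wise by construction, which is precisely the coherence the
shared-parameter model assumes. There is no dropout (exposure is exactly
$nT$), no time-varying hazard, and no within-patient rate change after the
first event, matching the models' assumptions; real data violate several of
these, so passing recovery tests demonstrates correctness of the machinery,
not robustness to overdispersion.

`basal_insulin_config()` fixes the study conditions the package is tested
under: 8 regimens, 20 two-arm trials, 12 reporting both formats, 4 risk-only
and 4 rate-only, comparators cycling over treatments 2–8 against the
reference so every analysis subset is connected, reference rate 0.38 events
per person-year, true $|\log \mathrm{HR}| \leq 0.3$, $\sigma = 0.3$, and
50–500 patients per arm (per-study sizes are not published for the
motivating dataset; this range is typical of insulin trials). Follow-up is
drawn log-uniformly between 4 weeks and 2 years: trial durations in this
literature cluster at the short end (the motivating evidence base averaged
about five months), and a log-uniform draw reproduces that (mean ≈ 0.6
years) where a uniform draw would average just over a year.

## Numerical and design choices

* Follow-up is converted to years at 52.18 weeks/year and 12 months/year;
  the cloglog offset is the natural log of follow-up in years, so hazard
  ratios are per-year and commensurate with the Poisson person-year scale.
* Credible intervals are equal-tailed percentile intervals (2.5%/97.5%)
  throughout; relative effects are summarised by posterior medians.
* The reference row of a relative-effects table is exactly 1, and
  re-referencing subtracts draws before exponentiating.
* Treatments absent from the records a model consumes, or a disconnected
  comparison graph, raise an estimability error rather than a silent
  partial fit.
* Degenerate inputs are defined: zero event cells (Bayesian likelihoods and
  the deviance conventions handle them), $t = 0$ horizons (probability 0),
  single-study networks, and single-draw posteriors ($p_D = 0$).
* JAGS adaptation uses half the burn-in (at least 100 iterations), with the
  remainder as explicit burn-in.

Problem sizes in the test suite are chosen to make Monte Carlo error small
relative to the tolerances: large-count single studies (1000–100,000 per
arm) for maximum-likelihood limits, the 20-study default configuration for
end-to-end properties, 50 replicated networks (2 chains × 1500 draws each)
for interval coverage of $d$ and bias of $\sigma$, and short 2-chain runs
for plumbing tests where only determinism matters.

## Known limitations

* No meta-regression or covariate adjustment, no negative-binomial
  likelihood for overdispersed rates, and no arm-based (as opposed to
  contrast-based) models.
* Inconsistency assessment is global (unrelated mean effects); there is no
  node-splitting.
* The simulator's homogeneous process cannot reproduce the
  rate-versus-first-event-hazard gap seen in real severe-hypoglycaemia
  data, as discussed above.
* Costs and disutilities are one-year, single-event-type quantities; no
  QALY aggregation over longer horizons is attempted.
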