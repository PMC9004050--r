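---
title: "Methods: LLIN durability, attrition and Bayesian survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LLIN durability, attrition and Bayesian survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llindur)
```

## The problem

Long-lasting insecticidal nets (LLINs) are distributed in mass campaigns on
the assumption of a roughly three-year useful life. Whether a net actually
protects anyone three years later depends on two distinct processes:
physical decay (holes accumulate until the net is torn) and household
attrition (the net is given away, stolen, exchanged, discarded, or
repurposed). `llindur` analyses longitudinal cohorts in which individually
identified nets are revisited at a fixed round grid — by default 6, 12, 24
and 36 months after distribution — and each net is recorded present,
discarded, or not found, with hole counts taken on present nets.

## Physical integrity: the proportionate hole index

Holes are counted in four WHO diameter classes (0.5–2 cm, 2–10 cm, 10–25 cm,
\> 25 cm) and combined into the proportionate hole index

$$\mathrm{pHI} = n_1 + 23\,n_2 + 196\,n_3 + 576\,n_4,$$

whose weights approximate the relative damaged area of a typical hole in
each class. Nets are classified Good (pHI ≤ 64), Damaged (65 ≤ pHI ≤ 642) or
Torn (pHI > 642), and a net is *serviceable* while pHI ≤ 642 (roughly, less
than 1000 cm² of destroyed surface; the integer rule is the operational
one). The weights and thresholds are hard-coded constants rather than
configuration: they define the scheme, and making them tunable invites
silent divergence between analyses. Holes whose diameter falls exactly on a
class boundary (2, 10, 25 cm) are not assigned by the scheme itself; this
package takes class counts as given and never re-derives them from measured
diameters.

## Cohort cleaning: a monotone status lattice

Raw observations are reorganised into a nets × rounds matrix with cells in
{PRESENT, DISCARDED, NOT_FOUND, UNKNOWN, UNSURVEYED}. Three deterministic
rules are applied, in this order:

1. **Backfill presence.** A net present at some round was present at every
   earlier round, observed or not: all cells before the last PRESENT cell
   become PRESENT.
2. **Forward discard.** Discard (destroyed or repurposed) is absorbing: all
   cells after a DISCARDED cell become DISCARDED.
3. **Mark unknown.** A NOT_FOUND report that precedes a later DISCARDED
   report is genuinely ambiguous — the net may or may not already have been
   destroyed at that round — and becomes UNKNOWN.

The order matters: backfilling first removes spurious NOT_FOUND cells that a
later sighting contradicts, so that rule 3 only marks cells whose ambiguity
survives all deterministic information. The composed pipeline is a fixpoint
(applying it twice changes nothing), which the test suite checks on
hand-built trajectories covering all rule interactions and on simulated
cohorts. A PRESENT cell at or after a DISCARDED cell violates the absorbing
state; it is surfaced as an error naming the offending nets rather than
silently repaired, since no repair rule can be justified from the data.

Rounds at which a household was not visited are UNSURVEYED, not NOT_FOUND:
the net's fate carries no information there, and those cells are excluded
from all per-round denominators. (Treating "household not found" as an
absence instead would conflate survey logistics with attrition; the
alternative convention is noted here precisely because the choice is a
convention.)

## Attrition accounting and rates

- **Reason breakdown.** Nets absent at a round are tabulated by the first
  recorded cause (given away, stolen, exchanged, damaged-and-discarded,
  repurposed); percentages are over the attributable absent total. Absent
  nets with no recorded cause are counted separately and excluded from the
  percentages.
- **Survival rate** = present *and serviceable* nets / (present +
  discard-family losses). The give-away family is excluded from the
  denominator because those nets' ultimate fate is unknown (most are
  probably in use elsewhere); the rate therefore isolates loss to physical
  wear.
- **Retention rate** = present nets / (present + give-away-family losses);
  the discard family is excluded, so the rate isolates whether households
  keep nets.
- UNKNOWN cells are excluded from both rates: whether the net was present is
  exactly what is not known. Their resolution belongs to the Bayesian model.
- Present nets without a pHI measurement (e.g. backfilled cells) count as
  serviceable in the survival rate: their presence is established, their
  damage unobserved. With heavy missingness this can bias the survival rate
  upward slightly; the model-based estimates do not share this convention.
- Confidence intervals are two-sided 95% Wilson score intervals
  (`prop.test(correct = FALSE)`), which behave sensibly at the small
  denominators of late rounds where a shrinking cohort can otherwise
  produce degenerate Wald intervals.

**Median survival time.** With rates $p_1, p_2$ (percent) at times $t_1,
t_2$ (years), $T_m = t_1 + (t_2 - t_1)(p_1 - 50)/(p_1 - p_2)$. The CI
applies the formula to the two lower limits and to the two upper limits
respectively. Two flags are attached rather than hidden: a
`projection_warning` when $p_1 > 85$ (projection toward the median from so
high a first point is unreliable), and `extrapolated` when the crossing
falls outside $[t_1, t_2]$ — the formula supports extrapolation and cohort
analyses routinely report medians beyond the second time point, but the
linearity assumption is then untested. $p_1 = p_2$ is a degenerate slope and
an error, not an NA.

## The Bayesian discrete-time survival model

**Likelihood.** Failure is *absence for any reason*: the event is the net
leaving the household, whether through wear or redistribution. (This is
deliberately different from the serviceability-based survival *rate* above;
the two answer different questions.) For net $i$ of brand $b$ in household
$h$, each interval $k$ it is at risk in contributes a Bernoulli term with

$$\operatorname{logit} \Pr(\text{present at } k \mid \text{present at } k-1)
 = \alpha_{b,k} \;(+\; \beta\,\mathrm{rural}_i) \;+\; u_h,
 \qquad u_h \sim \mathcal N(0, \sigma^2).$$

The per-brand variant estimates independent $\alpha_{b,k}$ per product and
interval; the zone variant pools products into interval intercepts
$\alpha_k$ and adds the rural coefficient $\beta$, so $e^\beta$ is the
rural-vs-urban odds ratio of interval survival. The logit link makes the
reported odds ratio exact rather than approximate. Unequal interval lengths
(6, 6, 12, 12 months) are handled by giving each interval its own parameter
— per-round survival is what the data identify — rather than rescaling to a
constant hazard. UNSURVEYED tails are right-censored. A switch
(`censor_not_found`) instead censors give-away-family losses for analysts
who prefer to treat redistribution as non-informative censoring.

**Priors.** $\alpha_{b,k}, \beta \sim \mathcal N(0, 2.5^2)$ (weakly
informative on the logit scale: survival probabilities between 0.7% and
99.3% within one prior SD), $\sigma \sim$ half-Normal(1). In the conjugate
mode (below) interval survivals get Beta(1, 1).

**Data augmentation.** After cleaning, a net last surely present at round
$a$ and first surely absent at round $d$ has a latent failure interval $f
\in \{a+1, \dots, d\}$; the UNKNOWN and interleaved UNSURVEYED cells in
between are exactly what $f$ determines. Its full conditional is

$$\Pr(f = j) \propto \Big(\textstyle\prod_{k=a+1}^{j-1} p_k\Big)(1 - p_j),$$

implemented in `failure_interval_probs()` and sampled afresh in every Gibbs
iteration. Presence after a DISCARDED assignment has probability zero by
construction, and every imputed trajectory is monotone (present before $f$,
absent from $f$ on) — an invariant the tests check on every retained
iteration. The degenerate conditional where every $p_k = 1$ (possible under
extreme parameter draws) resolves to failure at the earliest interval and is
counted in the fit object (`n_degenerate`).

**Sampler.** Gibbs over latent states with conditional parameter updates:

- conjugate Beta draws for the interval survivals when the per-brand variant
  is fitted without random effects (`household_re = FALSE`) — with no
  missing data this *is* the closed-form Beta posterior, which gives the
  test suite an exact oracle: posterior means must match
  $(\text{survivors}+1)/(\text{at risk}+2)$ within Monte-Carlo error;
- otherwise adaptive random-walk Metropolis-within-Gibbs on the logit
  scale. The $\alpha_{b,k}$ (and separately the $u_h$) are conditionally
  independent given everything else because each Bernoulli row touches
  exactly one of each, so all groups are proposed and accepted/rejected in
  parallel; proposal scales adapt toward ~40% acceptance during burn-in only
  (so the retained chain is a fixed-kernel Markov chain). $\sigma$ is
  updated by a log-scale random walk (with Jacobian); households with no
  observations draw $u_h$ exactly from the prior.

Defaults are 4 chains × 5,000 iterations with 2,500 burn-in; convergence is
summarised by split-half $\widehat R$ per parameter with a 1.01 flag
threshold (flagged, never fatal). Initial values: empirical
smoothed survival proportions (clipped to [0.05, 0.95] before the logit),
$u = 0$, $\beta = 0$, $f$ at its latest admissible round. Chains use
deterministic sub-seeds derived from the user seed, so every fit is exactly
reproducible.

A brand-interval cell with no data at all (e.g. a product that vanished at
the first round) is sampled from its prior with a warning — visible honesty
about which cells the data inform.

## The synthetic-cohort generator

`simulate_cohort()` emulates the study conditions the analysis assumes: by
default ~2,200 nets (1,700 households, mean 1.3 nets each, one product per
household) across 8 products and 2 zones, observed at 6/12/24/36 months.
Latent presence follows exactly the model's discrete-time process with
per-brand interval survivals (defaults spanning cumulative 24-month survival
of roughly 51–88%, near-100% first-interval survival), a rural log-odds
shift (default 0.924) and household effects (default SD 0.5). At failure a
cause is drawn from round-specific weights (defaults reflecting early losses
dominated by giving nets away and later losses by damage and theft); the
give-away family yields NOT_FOUND observations, the discard family
DISCARDED. Holes arrive as per-interval Poisson counts per size class
(default per-year rates 8/2/0.4/0.1, brand multipliers for fragile or robust
fabrics), so counts are nondecreasing for surviving nets. Missingness acts
at household level (defaults 0/0.25/0.50/0.95 per round, reproducing the
steep late-round denominator shrinkage typical of such cohorts).

Two reporting-noise mechanisms generate the ambiguity the cleaning rules
exist for: a discard-family loss may be reported NOT_FOUND at the first
post-failure visit before being confirmed DISCARDED later (default
probability 0.15), and a present net may occasionally be unlocatable at one
visit (default 0.02). Both create raw NOT_FOUND-before-DISCARDED patterns
that cleaning turns into UNKNOWN cells.

What the generator does **not** emulate: within-round event timing (all
transitions live on the round grid), informative missingness (visits are
independent of net status), net-use covariates (washing, sleeping spaces),
insecticide decay, and any spatial structure. Reporting noise is
non-informative in the model's likelihood, while in the generator a
NOT_FOUND-then-DISCARDED pattern is in truth more often an already-failed
net; passing parameter-recovery tests therefore shows the sampler handles
genuinely ambiguous cells correctly, not that real-world reporting is
non-informative. Passing tests on synthetic data show correctness of the
machinery under the stated process, not that field cohorts satisfy it.

## Problem sizes and numerical choices in the test suite

The suite exercises: exact arithmetic checks on printed-style count tables
(instantaneous); law-of-large-numbers checks on 10,000-net cohorts (3–3.5
binomial SEs); conjugate-oracle equivalence on a 500-net complete cohort (3
Monte-Carlo SEs per cell, 2 chains × 3,000 iterations); and a
parameter-recovery experiment of 20 replicate cohorts of 1,000 single-net
households (σ = 0.5, β = 0.9, 15% round missingness, 20% unconfirmed-discard
reporting; 2 chains × 1,500 iterations per fit), requiring the 95% credible
interval for β to cover the truth in at least 17 of 20 fits and pooled
coverage across all six parameters of at least 85%. These sizes were chosen
to make each statistical assertion's error bound explicit and small while
keeping a full run of the suite in the minutes range on one core.

## Known limitations

- The raw-rate estimators inherit the cohort's convention that backfilled
  presence counts as surveyed; with extreme missingness the survival rate
  leans on the serviceable-when-unmeasured convention.
- The zone variant pools brands; brand-by-zone interactions are out of
  scope, as are time-varying covariates.
- Metropolis updates of many weakly informed household effects mix slowly
  when households contribute one or two nets; σ's posterior is then prior
  sensitive. The recovery experiment quantifies this under the default
  prior.
- Median survival times interpolate exactly two time points; no survival
  curve is fitted, by design, since first-round rates above 85% make curve
  projection unreliable.
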