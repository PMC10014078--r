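---
title: "Inferring colonization bottlenecks from neutral barcodes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring colonization bottlenecks from neutral barcodes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrace)
```

## The problem

When a bacterial population colonizes the gut, only a fraction of the
inoculated cells found lineages that persist. Spiking a small, known number
of neutrally barcoded clones (wild-type isogenic tagged strains) into an
otherwise untagged inoculum turns this bottleneck into something measurable:
each barcode that disappears between gavage and endpoint records a founding
failure, and the drift of barcode proportions records how few founders the
surviving population descends from. `clonetrace` implements the estimators
that convert these readouts into a per-cell colonization probability
$\beta$, the competition model that links lag phases and net growth rates
to competitive indices, and a forward stochastic simulator that generates
synthetic experiments so every estimator can be validated without animal
data.

## The colonization model

One experiment is modelled in four stages.

**Inoculum.** A barcode with intended spike-in mean $n_0$ contributes a
Poisson$(n_0)$ number of cells to the dose, because the barcodes are a
vanishing volume fraction of the prepared suspension. With a per-cell
lineage-survival probability $\beta$, the probability that a barcode leaves
no surviving lineage is therefore exactly

$$p_{\mathrm{loss}} = e^{-\beta n_0}.$$

**Early killing.** Each cell independently survives stomach and
small-intestine transit with probability $q$. The data cannot distinguish
whether this killing is instantaneous or spread over transit; we model it
as instantaneous Bernoulli thinning at $t = 0$, which leaves all
endpoint-visible quantities unchanged.

**Growth.** Surviving founders arrive in the cecum, wait out a lag $\tau$
during which they are cleared at per-capita rate $c$ but do not divide,
then divide at rate $r (1 - B(t)/K)$ where $B(t)$ is the total population
density and $K$ the carrying capacity. Only the net rate
$\mathrm{net} = r - c$ is identifiable from total-CFU time courses; the
clearance component can be anchored independently through cecal turnover
(below).

**Measurement.** The pooled barcoded density is measured by serial-dilution
plating (Poisson colony counts, plates outside a 30–300-colony window
discarded, detection limit below which a tag is censored) and the barcode
composition by qPCR, modelled as multiplicative log-normal noise of stated
CV with a calling floor ($10^{-4}$ by default) below which a frequency is
zeroed before renormalization. The floor-then-renormalize rule is our
choice: how sub-limit qPCR signals should be treated is not dictated by the
assay, and the floor matches the roughly five-order dynamic range of the
plating/qPCR combination.

## Estimating the colonization probability

### From lost tags

Pooling barcode observations $i = 1,\dots,\omega$ across animals and
experiments (each with its own spike-in $n_i$), the log-likelihood is

$$LL(\beta) = \sum_{i=1}^{\omega} \left[ l_i \, (-\beta n_i) +
  (1 - l_i) \log\!\left(1 - e^{-\beta n_i}\right) \right],$$

with $l_i = 1$ for a lost tag. `beta_mle_loss()` maximizes this over
$\log\beta$ by golden-section search polished with the analytic score, so
the fit is deterministic and, when all $n_i$ are equal, matches the closed
form $-\ln(\hat p_{\mathrm{loss}})/n_0$ to near machine precision.

Confidence intervals are profile-likelihood intervals with
$\chi^2_1$ cutoffs: a log-likelihood drop of 1.92 for two-sided intervals,
1.35 for the one-sided bounds returned when every tag is lost (upper bound
$1.35/\sum n_i$) or every tag retained. For the all-retained bound we solve
$LL(\beta) = LL_{\max} - 1.35$ rather than $LL(\beta) = -1.35$; the two
coincide for large $n_i$ (where $LL_{\max} \approx 0$) but only the former
is well-defined for small spike-ins. The exact interval construction is a
design choice of this package and is validated empirically: across
simulated cohorts at the study design the intervals cover the truth about
95% of the time (the test suite checks 93–97%).

A tag is called "lost" when its reconstructed density is censored at the
detection limit; no partial-detection states are modelled.

### From proportion variance

Barcode proportions drift away from the inoculum composition in inverse
proportion to the number of founders. For each animal,

$$v_m = h \left(\textstyle\sum_j n_{j,0}\right)
  \left(\mathrm{var}(p) - \mathrm{var}(p_0)\right)$$

estimates the relative variance contributed by a single founding cell,
which under Poisson founding plus stochastic early growth (each established
lineage acquiring an approximately exponential weight) has expectation
$2/\beta$. `beta_variance()` averages $v_m$ across animals, inverts
$\hat\beta = 2/\bar v$, and transforms the $\bar v \pm 1.96\,\mathrm{SE}$
interval through the monotone map $x \mapsto 2/x$, which preserves interval
ordering. Animals that lost every barcode carry no proportion information
and are dropped; a nonpositive mean excess variance is reported as a
degenerate lower-only bound. The sample variance uses the $1/(h-1)$
convention, with the mean proportion fixed at $1/h$ by construction.

### Spike-in design

The loss estimator is most robust when roughly half the tags are lost,
giving $n_0 = \ln 2/\beta$. The Fisher information of a single loss
observation, $\propto x^2/(e^x - 1)$ in $x = \beta n_0$, is instead
maximized at $x^* \approx 1.594$ (about 20% loss). `optimal_n0()` reports
both; the two criteria answer slightly different questions (robustness of
the pooled estimate versus per-observation information) and neither is
asserted as uniquely correct.

### After a challenge

A challenge applied to a population at carrying capacity bottlenecks
lineages rather than cells-at-gavage. With $n_0$ cells of a barcode present
at challenge start, the loss probability is $(1-\beta)^{n_0}$ where $\beta$
is now the per-cell lineage-survival probability through the window.
`challenge_beta()` maximizes and profiles this binomial likelihood exactly
as in the loss method. Pre-challenge cell numbers are reconstructed from
day-0 fecal densities via the control-arm feces-to-cecum concentration
ratio and the wet cecal mass (`estimate_day0_n0()`); tags below detection
at day 0 are excluded from the likelihood.

## The competition model

With equal replication rates $r_w = r_a$ (supported in vitro) and clearance
acting during the lag, the endpoint abundance ratio of two strains is

$$CI = \frac{q_w}{q_a}
  \exp\{(\mathrm{net}_w + c_w)(\tau_a - \tau_w)\}
  \exp\{(\mathrm{net}_w - \mathrm{net}_a)\, t_{tot}\}.$$

The sign convention is fixed by the biology: the slower strain declines in
frequency continuously, so $CI$ grows with $t_{tot}$ whenever
$\mathrm{net}_w > \mathrm{net}_a$. The formula is exact under the shared
logistic birth factor whenever total density is far below $K$ during the
lag-difference window — both before saturation (both strains share the same
birth factor, so the log-ratio changes at rate
$\mathrm{net}_w - \mathrm{net}_a$) and after it (the bulk's replication
compensates $c_w$, leaving the focal strain declining at $c_a - c_w$, the
same rate). The package checks this against `solve_competition()`, a
`deSolve` integration of the two-strain ODEs, across a 100-point parameter
sweep at 1% tolerance.

For the competition-conditional colonization probability, once the bulk
reaches carrying capacity every focal lineage is a linear birth-death
process with birth $c_w$ and death $c_a$, so

$$\beta_{comp} = \beta_{single}\left[1 - p_{ext}(c_w, c_a, t_{tot} -
t_K)\right],$$

with the standard closed-form extinction probability
(`extinction_probability_bd()`). Because a smooth logistic never attains
$K$ exactly, $t_K$ is defined as the time the deterministic bulk trajectory
reaches 95% of its effective plateau; the precise definition matters little
because the post-saturation decline dominates.

## Growth-curve fitting

Fecal time courses are fitted with the piecewise model
$N(t) = \min(K, N_a e^{\mathrm{net}\,\max(0, t-\tau)})$ by least squares on
the $\log_{10}$ scale. Censored points (below the detection limit)
contribute a one-sided quadratic penalty whenever the fitted curve rises
above the limit there. The lag is profiled over a deterministic 25-point
grid and the best candidate polished by a joint bounded quasi-Newton
refinement, so the fit is reproducible without randomness. The plateau is
estimated jointly; when no observation comes within 0.1 $\log_{10}$ of the
fitted plateau the plateau is declared unidentified and pinned to the
maximum observed density (flagged in the result). Whether the original
analysis estimated the plateau jointly or fixed it is not documented; joint
estimation with this fallback reproduces both regimes. Time courses whose
uncensored points span less than half a decade are rejected as
plateau-only: the net rate is not identifiable from them.

## The simulator as oracle

`simulate_colonization()` implements the model above literally: Poisson
inoculum, Bernoulli thinning, then for each barcode a continuous-time
birth-death clone simulated by exact thinning (Ogata) against the
time-varying birth rate, switching to deterministic growth once the clone
exceeds $10^4$ cells, where extinction risk is negligible and the
stochastic weight of the lineage is already fixed. The untagged bulk — and
the saturation term the clones feel — is a deterministic mean-field
trajectory (closed-form logistic with clearance and lag) seeded from the
untagged dose plus the expected tagged biomass. This is accurate because
tagged clones are at most $10^{-3}$ of the population in all study designs;
when the tagged clones themselves are a large population fraction the
mean-field cap is only correct in expectation, which the test suite
accommodates by using many founders in that regime. Clearance is modelled
as continuous exponential flow at the turnover-derived rate; the real cecum
empties in pulses, and pulsatility (like spatial structure, circadian
variation, immunity and phage) is out of scope.

Challenge windows use the exact endpoint law of the linear birth-death
process (binomial surviving-lineage count, geometric lineage sizes) instead
of event-by-event simulation, which makes clone sizes of $10^9$ cells
cheap while remaining exact.

Reproducibility: every user-facing simulation takes a master seed;
cohort simulations derive one sub-seed per mouse from it (a single
`sample.int` draw), so replicate sets are reproducible and individual mice
can be re-simulated in isolation. Fixed seed gives bit-identical output.

What the generator does *not* emulate — cage effects, inter-animal
parameter variation, barcode fitness differences, qPCR primer biases —
bounds what passing tests show: they demonstrate that the estimators invert
the stated model at realistic noise levels, not that the model captures
every feature of real data.

## Cecal turnover

`cecal_turnover()` is deliberately plain arithmetic: wet excretion
$=$ dry excretion $/(1 -$ water fraction$)$, assuming minimal change in dry
mass during colon transit; dividing by wet cecal mass gives volumes/day and
volumes/hr. Germ-free physiology (water fraction 0.809, dry excretion
1.55 g/day, wet mass 2.83 g) gives 0.12 volumes/hr; conventional (SPF)
physiology gives 0.18 volumes/hr. These anchor the clearance defaults:
low-complexity-microbiota animals fall between the two, and the package
leaves interpolation to the user rather than guessing.

## Numerical choices and problem sizes

* Likelihood optimization: golden-section over $\log\beta \in
  [\log 10^{-9}, 0]$, score-polished; profile roots by `uniroot` at
  tolerance $10^{-14}$. No randomness anywhere in estimation.
* Hybrid switch at $10^4$ cells; validated against pure Gillespie runs
  (endpoint means within 5% on a $10^4$-cell niche).
* Birth-rate tables on a 2001-point time grid; the thinning bound uses the
  running maximum of the tabulated rate, so the algorithm stays exact for
  non-monotone rates (the bulk dips during its lag before growing).
* ODE cross-checks use `lsoda` at `rtol = 1e-10`.
* Validation problem sizes were chosen to hold Monte-Carlo error well below
  the tolerances being asserted while keeping the default suite fast:
  100 cohorts of 15 mice for estimator recovery (both
  $\beta \in \{0.03, 3\times10^{-3}\}$), 200 pooled cohorts for interval
  coverage, $10^5$ lineages for the extinction-probability cross-check,
  1000 replicates for hybrid-versus-pure comparison, 100 replicates for
  growth-fit recovery.

## Known limitations

* The mean-field bulk makes tagged-clone endpoints exact only when tags are
  a small population fraction; the regime the design targets.
* The variance estimator's $2/\beta$ relation assumes established lineages
  acquire approximately exponential weights; at very small spike-ins
  ($n_0 \approx \ln 2/\beta$, i.e. under one founder per tag) it retains a
  positive bias of order 10%, within the documented tolerance but visible.
* Profile intervals are asymptotic; with 90 binary observations their
  coverage is close to, but not exactly, nominal (about 95.5% at the study
  design).
* Competitive-index predictions assume equal replication rates; with
  unequal $r$ the saturation phase changes the log-ratio drift and the
  closed form no longer applies.
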