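# clonetrace

Inference of colonization bottlenecks, growth dynamics and
challenge survival from neutrally barcoded bacterial strains.

## What problem this solves

When bacteria colonize the gut, most inoculated cells never found a
persistent lineage. Spiking a handful of neutral chromosomal barcodes
(wild-type isogenic tagged strains, WITS) into an untagged inoculum makes
this bottleneck measurable: a barcode spiked at mean dose `n0` leaves no
surviving lineage with probability `exp(-beta * n0)`, where `beta` is the
per-cell colonization probability — the chance that one inoculated cell
founds a lineage still detectable at the endpoint. `clonetrace` is for
microbiologists and modellers running such experiments in gnotobiotic
animals: it estimates `beta` (with confidence intervals) from barcode loss
or from barcode-proportion variance, designs the spike-in size, fits
lag/net-growth parameters from CFU time courses, predicts competitive
indices from those parameters, quantifies post-challenge lineage survival,
and ships a forward stochastic simulator that generates complete synthetic
experiments so every estimator can be validated end to end.

## The core statistics

**Loss method.** Barcode observations `i = 1..w`, each with spike-in mean
`n_i` and loss indicator `l_i`, give the log-likelihood

    LL(beta) = sum_i [ l_i * (-beta * n_i) + (1 - l_i) * log(1 - exp(-beta * n_i)) ]

maximized deterministically over `log(beta)`; 95% CIs by profile
likelihood (drop of 1.92; one-sided bounds with 1.35 when all tags are
lost or all retained). Equal spike-ins recover the closed form
`-log(fraction lost)/n0`.

**Variance method.** Per animal, `v = h * sum(n0) * (var(p) - var(p0))`
estimates the relative variance contributed by one founding cell, with
expectation `2/beta`; averaging across animals and inverting gives an
independent estimate of the same `beta`.

**Competition model.** With equal replication rates and clearance acting
during the lag, two strains' endpoint ratio is

    CI = (q_w/q_a) * exp((net_w + c_w) * (tau_a - tau_w)) * exp((net_w - net_a) * t_tot)

**Challenge survival.** A barcode carried by `n0` cells at challenge start
is lost with probability `(1 - beta)^n0`; the same likelihood machinery
returns the per-cell lineage-survival probability through the challenge.

## Worked example

Simulate a 15-mouse cohort at the half-loss design for a true
colonization probability of 0.03 (six barcodes at 23 CFU each inside an
untagged dose of 1e7), then recover `beta` both ways:

```r
library(clonetrace)
design   <- inoculum_design(rep(23, 6), untagged_dose = 1e7)
dynamics <- strain_dynamics(q = 0.03, r = 0.62, c = 0, tau = 3.2)
cohort   <- simulate_cohort(design, dynamics, competition_state(),
                            n_mice = 15, seed = 42)

summary(beta_mle_loss(tag_loss_table(cohort)))
#> Colonization probability estimate (loss method)
#>   beta = 0.03418  [95% CI 0.02532 - 0.04503]
#>   n = 90 barcode observations
#>   log10(beta) = -1.47 +/- 0.13 (2 SD)

beta_variance(proportion_matrix(cohort), sum(design$barcode_means))
#> Colonization probability estimate (variance method)
#>   beta = 0.04116  [95% CI 0.03086 - 0.06178]
#>   n = 14 barcode observations
```

Both estimators bracket the simulated truth (0.03); the loss method used
all 90 barcode observations, the variance method the 14 mice that retained
at least one barcode. Design the next experiment's spike-in:

```r
optimal_n0(0.03)
#> $n0_half_loss  23.1      # half the tags lost
#> $n0_fisher     53.12     # Fisher-information optimum (~20% lost)
```

Physiology-anchored clearance and the predicted 48-hr competitive index
for a strain pair differing in lag (3.2 vs 7.7 hr) and net growth
(0.50 vs 0.40 /hr):

```r
cecal_turnover(gut_physiology(0.809, 1.55, 2.83))
#> $wet_excretion    8.12   # g/day
#> $turnover_per_day 2.87   # volumes/day
#> $turnover_per_hr  0.119  # volumes/hr

wt <- strain_dynamics(q = 0.03, r = 0.62, c = 0.12, tau = 3.2)
ac <- strain_dynamics(q = 0.03, r = 0.62, c = 0.22, tau = 7.7)
predict_competitive_index(wt, ac, 48)
#> [1] 1978
```

A wildtype advantage of ~2000-fold from a 4.5-hr lag difference plus a
0.1/hr net-rate difference compounded over 48 hr.

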