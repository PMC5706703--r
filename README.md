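# catchnet

Bayesian cue-weighting analysis for sensorimotor estimation
("candy-catching") experiments, built for researchers studying how
children — including clinical groups such as children with cerebral
palsy (CP) — combine learned prior information with noisy sensory
evidence.

## The problem and the model

On each trial a hidden target position *s* (in screen-width units, the
screen spanning [0, 1]) is drawn from a Gaussian prior N(μ, σs²); the
subject sees a "splash" of n = 4 dots drawn from a Gaussian likelihood
N(s, σl²) and places a net where they think the target fell. The ideal
observer combines the splash centroid c with the prior by precision
weighting:

    posterior mean = w·c + (1 − w)·μ,   w = σs² / (σs² + σl²/n)

A subject's actual reliance on the likelihood — the **estimation
slope** — is estimated per condition by regression of responses on
centroids through the origin in μ-centred coordinates:

    ŵ = Σ (cᵢ − μ)(ŝᵢ − μ) / Σ (cᵢ − μ)²

so ŵ ≈ 1 means "follow the splash" and ŵ ≈ 0 means "always point at the
prior mean". The package provides:

* the ideal-observer benchmark (`optimal_slope`, `posterior_params`,
  `chance_level`);
* a synthetic two-group cohort simulator with known reliance weights,
  motor noise and lapses (`simulate_cohort`, `observer`, `group_spec`);
* the slope model with trial-level percentile bootstrap CIs
  (`estimation_fit`, with `coef`/`summary`/`predict`/`residuals`/
  `plot`/`simulate` methods);
* rank-based group inference: an exact Wilcoxon signed-rank
  (`wilcoxon_signed_rank`), Bonferroni correction, and the
  Scheirer–Ray–Hare factorial rank test (`scheirer_ray_hare`), bundled
  by `cohort_tests`;
* CSV/JSON I/O with a column-mapping adapter for deposited data sets
  (`read_trials`, `write_trials`, `read_config`) and an end-to-end
  pipeline (`run_pipeline`, plus a CLI in `inst/scripts/`).

## Worked example

```r
library(catchnet)
trials <- simulate_cohort(n_per_group = 9, seed = 1)   # 9 CP + 9 TD
fit <- estimation_fit(trials, n_boot = 1000, seed = 24)
summary(fit)
cohort_tests(fit, chance = 0.02)
```

```
Task performance p(correct):
 group p_correct.median p_correct.mean
    CP           0.0958         0.0977
    TD           0.1500         0.1535
== Performance vs chance (0.02) ==
[CP] Wilcoxon signed-rank: statistic = 0, p = 0.00195 (adjusted 0.00391)
[TD] Wilcoxon signed-rank: statistic = 0, p = 0.00195 (adjusted 0.00391)
== Between-group performance ==
Wilcoxon signed-rank (paired, CP vs TD): statistic = 45, p = 0.00391
== Estimation slopes: Scheirer-Ray-Hare ==
                 effect df        ss      H  p_value
                  group  1  2028.000  2.067    0.150
                  prior  1 21336.333 21.750 3.11e-06
             likelihood  2 44665.722 45.531 1.30e-10
```

Reading the output: both simulated groups catch targets far above the
2% chance level (W = 0 — every subject beats chance — with exact
one-sided p = 2⁻⁹, Bonferroni-doubled), the TD group outperforms the CP
group on every age-matched pair, and the rank-factorial test shows
strong prior and likelihood main effects on the estimation slope —
subjects use both sources of information, weighting the splash less as
it gets wider and more when the prior is wide.

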