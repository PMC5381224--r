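# crowdmix

Analysis tools for **continuous-report visual crowding experiments**:
method-of-adjustment tasks in which an observer reproduces the gap
orientation of a peripheral Landolt-C target that is surrounded by ring
flankers. Identification of a peripheral target deteriorates sharply in
clutter ("crowding"), and single-trial continuous reports make it possible
to ask *how* it deteriorates: does the flanker add orientation noise
(positional uncertainty), pull the percept toward itself (featural
averaging), or replace the target outright (source confusion /
substitution)? `crowdmix` is written for psychophysicists who run such
experiments — or want to evaluate the estimators behind them on synthetic
data before trusting them on real observers.

## What the package computes

A trial yields a wrapped report error \(e_i \in (-180°, 180°]\) (reported
minus true target gap orientation, positive clockwise) and a
target–flanker gap offset \(\delta_i\). The analyses are:

- **Perceptual error** for featureless (no-gap) flankers: the circular
  standard deviation \(\sqrt{-2\ln R}\) of report errors (with \(R\) the
  mean resultant length), with 95% percentile-bootstrap CIs.
- **Trial-wise nearest-model labelling**: each error is assigned to the
  nearest of three model predictions — target (\(e=0\)), average
  (\(e=\delta/2\)) or substitution (\(e=\delta\)) — by circular distance,
  and per-condition proportions are tabulated.
- **Far-gap analysis** for two-gap flankers: errors \(|e| > 90°\) are
  attributed to the flanker gap opposite the target, counted per
  condition, re-centred by 180°, and relabelled against the far gap.
- **Mixture-model MLE** (`fit_mixture()`): maximises
  \[\sum_i \log\Big[(1-\beta-\gamma)\, f_\kappa(e_i) + \beta\,
  f_\kappa(e_i-\delta_i) + \gamma/360\Big],\]
  with \(f_\kappa\) a von Mises density on the 360° circle and shared
  concentration \(\kappa\); an averaging-extended variant adds a
  component at \(w\delta_i\) and flags its own weak identifiability.
- **A grid-search simulation estimator** (`monte_carlo_proportions()`)
  that scores candidate target/substitution proportions by the
  two-sample Kuiper distance between observed and simulated error
  distributions.
- **Linear slope fits** (`linear_slope()`), with the caveat attached
  that a target+substitution mixture mimics the slope-0.5 signature of
  averaging.
- **A parameter-recovery study** (`run_recovery_study()`) that validates
  every estimator on 100-trial synthetic datasets with known ground
  truth, generated by `simulate_validation_dataset()`.

A generative observer model (`observer_model()` +
`simulate_experiment()`) reproduces the experiment's structure — 16
conditions (unflanked + {no-gap, one-gap, two-gap} × 5 separations), 20
repetitions per condition per session, 5 sessions, flanker-gap offsets
drawn with SD 22.5° around the target and a second gap centred 180°
away — so every analysis stage is testable without real data.

## Worked example

Simulate one observer whose reports mix all strategies, then analyse the
most crowded one-gap condition:

```r
library(crowdmix)

model  <- observer_model(p_target = 0.45, p_average = 0.15,
                         p_sub_near = 0.25, p_sub_far = 0.05,
                         p_guess = 0.10, noise_sd_deg = 14)
trials <- simulate_experiment(model = model, observer_id = "N1", seed = 1)
one    <- trials[trials$flanker_type == "one_gap" &
                 trials$edge_separation_deg == 0.4, ]

fit_mixture(one$error_deg, one$delta1_deg, seed = 2)
#> Circular mixture model (standard), n = 100 trials
#>       p_target p_substitution        p_guess          kappa
#>         0.3296         0.4453         0.2251        21.8793
#>   circular SD: 12.39 deg; log-likelihood: -486.487 (20 restarts)

label_proportions(one)[, c("label", "proportion", "n")]
#>          label proportion   n
#> 1       target       0.36 100
#> 2      average       0.16 100
#> 3 substitution       0.48 100
```

The mixture fit and the labelling agree that under heavy crowding this
observer reported the flanker gap on nearly half the trials; the
two-component mixture folds the generative averaging mass into its
target and substitution shares (it has no averaging component), and at
100 trials both are estimates, not truth — `run_recovery_study()`
quantifies exactly how far off each estimator runs at this sample size.
The linear summary of the same data illustrates why slope fits mislead:

```r
linear_slope(one$error_deg, one$delta1_deg)
#> Linear fit: error = -5.423 + 0.7516 * delta  (R^2 = 0.113, n = 100)
```

a slope between 0.5 and 1 even though the generative model contains only
15% true averaging.

`run_analysis(trials)` runs every condition's analysis in one call and
returns tidy per-condition tables; `read_trials()`/`write_trials()`
round-trip real data through the documented CSV schema.

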