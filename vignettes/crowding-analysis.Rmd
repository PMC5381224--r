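---
title: "Methods: error taxonomy and mixture inference for continuous-report crowding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: error taxonomy and mixture inference for continuous-report crowding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdmix)
```

## The experimental setting

A Landolt-C target (an annulus with a gap) is shown 10° into the
periphery; the observer then rotates a matching foveal C until its gap
orientation reproduces what they perceived. The gap position is unique
on the full 360° circle, so every trial yields a continuous circular
report. The target may be surrounded by a ring flanker with no gap, one
gap, or two gaps, at one of five edge-to-edge separations (0.4° to
3.9°), or no flanker at all — 16 conditions. Flanker-gap orientations
are not arbitrary: the near gap is drawn from a normal distribution
centred on the target orientation with SD 22.5° (the range producing
strong crowding), and in the two-gap condition a second gap is drawn
centred 180° from the first with the same SD.

All angular bookkeeping in the package uses one convention: absolute
orientations live on [0°, 360°); differences — report errors and
target–flanker offsets — are wrapped into (−180°, 180°], positive
clockwise, with −180° mapping to +180°. `proportional_radius()` uses the
flanker *outer* radius, `(target_diameter/2 + separation)/eccentricity`;
this reading reproduces the conventional condition labels 0.14–0.49
(fractions of eccentricity), whereas a line-width-midpoint radius would
not, which is why we adopt it.

## The error taxonomy

Crowded continuous reports are heterogeneous. Three descriptive report
types are distinguished, as *descriptions of data*, not mechanisms:

* **target reports**, centred on the true orientation (error 0);
* **average reports**, centred between target and flanker gap
  (error δ/2 for weight 0.5);
* **substitution reports**, centred on the flanker gap (error δ).

`nearest_model_label()` assigns each trial to the prediction nearest its
error by circular distance. Ties are broken by the fixed priority
target > average > substitution; the priority is arbitrary but
deterministic, and the bias any such rule induces is exactly what the
recovery study measures. Circular rather than linear distances are used
so that re-centred far-gap data (below) behave identically; for
|δ| ≤ 90° the two coincide.

Labelling is deliberately simple and has a known bias: when the
generative report distribution is a single component centred on the
target and offsets are small relative to the report noise, noise alone
pushes errors past the average and substitution boundaries (at δ/4 and
3δ/4), so the labelled target proportion *underestimates* a pure-target
observer. The package asserts this regime in its tests (generative
target probability 1, offsets with SD 22.5°, noise SD 15°) rather than
hiding it: users should read labelled proportions near the extremes with
that bias in mind.

### Two-gap trials: far-gap split and re-centering

With a second gap opposite the target, errors form two clusters —
around 0° and around ±180°. Reports with |error| strictly greater than
90° are classified as far-gap reports (the threshold is a definition,
not an estimate; exactly 90° counts as near). The far subset is
re-centred by subtracting 180° from both the error and the target–far-gap
offset, after which an error of 0° means a report of the target's polar
opposite and the same three-model labelling applies with the far-gap
offset as the model axis. Far subsets are small (a handful of trials per
condition at wide separations), so the far analyses pool observers by
default (`analysis_config(pool_far_observers = TRUE)`) and every summary
row carries its n; no smoothing is applied.

## The mixture model

`fit_mixture()` is the model-based counterpart: errors are modelled as a
mixture of a von Mises component at 0 (probability 1−β−γ), a von Mises
component at the per-trial offset δᵢ (probability β), and a uniform
guess (probability γ), with one shared concentration κ. The von Mises
is parameterised on the 360° circle — the gap position does not have the
180° periodicity of gratings. Offsets enter trial-by-trial because the
design varies them across trials; collapsing them to one fixed offset
would misstate the likelihood.

Numerical choices:

* Optimisation is bounded quasi-Newton (L-BFGS-B) on transformed
  parameters — softmax logits for the proportions, logit for the
  averaging weight, log κ — because the likelihood is multimodal.
  20 random restarts (50 for the averaging variant) are drawn from a
  seeded RNG; the best restart is returned with per-restart
  log-likelihoods.
* κ is confined to [0.01, 500] so the likelihood stays finite on
  degenerate data; an estimate on a bound is flagged
  (`kappa_on_bound`). κ = 500 corresponds to a circular SD of about
  2.6°, well below any plausible report noise.
* Mixture densities are floored at 10⁻³⁰⁰ before the log, so a stray
  point cannot produce −∞ during optimisation.
* `kappa_to_circ_sd()`/`circ_sd_to_kappa()` convert between κ and the
  circular-SD scale via the Bessel ratio R(κ) = I₁(κ)/I₀(κ), inverted
  by monotone root-finding to 10⁻¹⁰; exponentially scaled Bessel
  functions keep both ends stable.

The **averaging-extended** variant adds two parameters: an averaging
probability and its weight w, giving a component at wδᵢ. On small
two-component samples this model is weakly identified — the averaging
component can trade off against the target component almost freely. The
fit therefore computes its own instability diagnostic: the numerical
Hessian of the negative log-likelihood at the optimum (in transformed
space) and the spread of the averaging proportion across restarts within
2 log-likelihood units of the best. The fit is flagged `unstable` when
the Hessian is singular, non-finite or has condition number above 10⁶,
or when that spread exceeds 0.2. These cutoffs were fixed as part of the
diagnostic's definition; on 100-trial two-component data the flag fires
on essentially every replicate, which is the behaviour the recovery
study expects of it.

## The grid-search simulation estimator

As a likelihood-free cross-check, `monte_carlo_proportions()` searches
the two-component proportion simplex on a grid (step 0.05). Each
candidate (p_target, 1−p_target) is scored by simulating 200 replicate
datasets of the observed size — reusing the observed offsets and a
supplied noise SD — pooling the simulated errors, and computing the
two-sample Kuiper distance to the observed errors; the minimising cell
is returned with the whole score surface. The Kuiper statistic (the
rotation-invariant Kolmogorov–Smirnov variant) is used because errors
are circular and the score should not depend on where the circle is cut.
The noise SD is an input, not a search dimension: estimate it from
unflanked or no-gap trials with `circular_sd()`. This estimator is a
reconstruction built to the two-component description above; its
reliability is established empirically by the recovery study rather
than asserted.

## The generative observer and what the simulations show

`simulate_experiment()` emulates the design faithfully: 16 conditions ×
20 repetitions × 5 sessions = 1600 trials (100 per condition), uniform
target orientations, gap sampling exactly as in the stimulus program,
randomised trial order within session, and reports drawn from an
`observer_model()` mixture over target / average / near-substitution /
far-substitution / guess strategies with circular noise. Components
that need a gap the condition lacks are renormalised away. Ground-truth
strategy labels are stored per trial so estimators can be scored against
them; real-data tables simply lack that column.

Choices where the design was open:

* **Target orientations are uniform** on the circle — the
  non-informative choice for a full-circle task.
* **Noise family**: the validation generator uses wrapped-normal noise
  (mirroring Gaussian-noise simulation) while the fitted models are von
  Mises; below ~30° SD the families are nearly indistinguishable, and
  below the SD floor representable by κ = 500 the sampler switches to
  wrapped normal outright. Part of what the recovery study demonstrates
  is that this family mismatch does not matter at these noise levels.
* **Averaging means** interpolate along the short arc, target + w·δ;
  offsets are concentrated (SD 22.5°) so arc ambiguity is immaterial.
* **The guess component gets no extra noise** — it is already uniform.
* **Validation offsets** are drawn from the experimental 22.5°-SD
  distribution by default, with `fixed_delta_deg` available for
  perfectly separated scenarios.

The generator emulates the statistical structure the analyses assume —
it does **not** model serial dependencies, adjustment dynamics or
response times, eccentricity anisotropies, learning across sessions, or
any retinotopic/population-coding mechanism. Passing tests on synthetic
data therefore validate the *estimators* under the stated assumptions;
they cannot certify those assumptions for any real observer.

## The recovery study

`run_recovery_study()` applies each estimator to replicate synthetic
datasets of the validation design — by default 100 trials, the size of
one real condition — and tabulates bias, MAE and RMSE of the estimated
target proportion. The package's acceptance checks run 100 replicates
of the (0.5, 0.5) scenario at noise SD 10° and require the standard
mixture and the grid-search estimator to recover proportions with
MAE < 0.15, while the averaging-extended model must raise its
instability flag on a majority of replicates. Larger-sample properties
(bias < 0.01 at n = 10,000 with a 90° fixed offset) are asserted in the
unit tests. Test problem sizes — 10,000 draws for sampler calibration,
10,000 (error, offset) pairs for the labelling oracle, 100,000 samples
for circular-SD consistency — were chosen so that sampling noise is an
order of magnitude below each tolerance.

## Bootstrap and other statistical conventions

Confidence intervals are percentile bootstrap (default 1000 resamples,
level 0.95), resampling trials with replacement; percentile rather than
BCa is a deliberate, documented simplicity — for the dispersion and
proportion statistics used here the difference is small relative to the
CIs themselves, and percentile intervals are transparent. Linear slope
fits are ordinary least squares on the wrapped errors without trimming;
offsets beyond ±90° trigger a warning because wrapping can then bend the
regression. The slope's interpretation (0 target, 0.5 average, 1
substitution) is printed with the explicit caveat that a 50/50
target+substitution mixture also produces slope 0.5 — E[e | δ] = 0.5δ —
so a mid-range slope is not evidence of averaging; the package
reproduces this spurious-averaging effect in its tests.

## Known limitations

* Proportion estimates from 100-trial conditions carry sampling error
  of several percentage points under the best estimator; per-condition
  CIs should always be consulted.
* The labelling underestimates target proportions when competing
  components are rare (see above); the mixture estimators are preferred
  near the extremes.
* The averaging-extended mixture should be treated as a diagnostic, not
  an estimator, at realistic sample sizes.
* The grid-search estimator's resolution is its grid step; its score
  surface should be inspected for flat valleys before trusting the
  argmin.
* Empirical per-observer results from any particular experiment are not
  bundled with the package; all shipped numbers are computed from the
  synthetic generator at run time.
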