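---
title: "Leaf radiative transfer, inversion, and surrogate modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leaf radiative transfer, inversion, and surrogate modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafoptics)
```

## The forward model

`leafoptics` simulates leaf directional-hemispherical reflectance and
transmittance with a generalized plate model of the PROSPECT-D family. A leaf
is `N` identical absorbing plates (`N` real-valued, `N >= 1`) separated by
air gaps. Six traits drive the model: the structure parameter `N`
(dimensionless), chlorophyll `CHL`, carotenoid `CAR` and anthocyanin `ANT`
contents (ug/cm^2), equivalent water thickness `EWT` (cm) and dry mass per
area `LMA` (g/cm^2). Brown pigment is excluded throughout: it matters only in
late senescence.

Per wavelength, the engine composes four pieces:

1. **Absorption.** `k(lambda) = sum_c C_c K_c(lambda) / N`, with `K_c` the
   specific absorption coefficient of constituent `c`
   (`total_absorption()`).
2. **Elementary-layer transmission.**
   `tau(k) = (1 - k) e^{-k} + k^2 E_1(k)` — the transmission of isotropic
   diffuse flux through an absorbing slab (`layer_transmission()`).
3. **One plate.** Fresnel interfaces averaged over the incidence cone:
   the top surface uses `tav(alpha, n)` with `alpha = 40` degrees (the
   plate-model convention, exposed as an argument), interior interfaces use
   the hemispherical `tav(90, n)`, and the interior exit transmissivity is
   `tav(90, n)/n^2` by reciprocity (`plate_single_layer()`).
4. **The stack.** The first plate is kept separate; the Stokes solution
   covers the remaining `N - 1` plates, evaluated as `b^m = exp(m log b)` so
   `m = N - 1` may be any non-negative real; the two systems are coupled by
   the two-stream adding formulas (`stokes_stack()`, `forward_spectrum()`).

Numerical choices: `E_1` uses a power series below 1 and a modified-Lentz
continued fraction above, giving ~1e-14 relative accuracy without an external
special-function dependency; `tav` is the closed-form conical average
(machine precision against Fresnel quadrature); the conservative branch
`r + t >= 1` of the Stokes solution switches to its analytic limit
`T = t / (t + (1 - t) m)`. The test suite checks all three against
independent quadrature, ray-summation and layer-adding oracles.

## Inversion and the regeneration cycle

`invert_spectrum()` estimates the six traits from a reflectance spectrum by
minimizing the unweighted RMSE between simulated and target reflectance over
the full grid (reflectance-only, the common practice when transmittance is
unmeasured; no wavelength weighting or sub-domain selection). The optimizer
is bounded quasi-Newton (L-BFGS-B) on unit-scaled traits with numerical
gradients, three restarts (a fixed mid-physiological initial point plus two
seeded perturbations), default bounds `N in [1, 4]`, `CHL in [0, 120]`,
`CAR in [0, 30]`, `ANT in [0, 40]`, `EWT in [0, 0.1]`, `LMA in [0, 0.05]`.
Two settings matter for the nearly flat carotenoid/anthocyanin directions:
the finite-difference step is 1e-7 on the unit scale and the convergence
factor is set to machine-level (`factr = 1`). With the optimizer's default
step of 1e-3 only about half of random noiseless draws recover all six
traits to 1e-3 relative error; with 1e-7 recovery is complete to ~1e-5.

`regeneration_cycle()` chains measured -> inverted traits (`p_inv`) ->
simulated spectra (`hsr_sim`) -> re-inverted traits (`p_re`) -> re-simulated
spectra (`hsr_re`), exactly those four arrows. Because `hsr_sim` lies on the
model manifold by construction, the second half of the cycle is an
idempotence test of the inversion: the package asserts
`max mean-relative-error(sim, re) < 1e-6` and per-wavelength Pearson
`r(sim, re) > 0.999` on 50 synthetic samples.

Per-wavelength comparison statistics (`mean_relative_error_profile()`,
`pearson_profile()`, `rmse_profile()`) treat the first argument as the
"measured" denominator role. Pearson is reported as `NA` (never silently 0)
where a column is constant; band flagging (`flag_low_accuracy_bands()`,
defaults `r < 0.8`, minimum width 10 nm) counts undefined as sub-threshold,
because constant near-zero reflectance columns are exactly the problem
bands. A zero denominator in the relative error raises an explicit
division-hazard error naming the wavelength; noisy synthetic data clipped to
[0, 1] can contain exact zeros, so in-band error evidence on such data
should use the Pearson or RMSE profiles.

## Broad-sense heritability

`variance_components()` fits the all-random entry-mean model
`value = mu + genotype + environment + genotype:environment + residual` by
REML (`lme4`), truncating components at zero. Technical repeats within a
replicate are averaged to one plot value first — the model has no repeat
term, so repeats are treated as technical measurements. For unbalanced data
the effective `n_e` and `n_r` entering

H^2 = sigma^2_g / (sigma^2_g + sigma^2_ge / n_e + sigma^2_eps / (n_e n_r))

are harmonic means of per-genotype counts (standard entry-mean practice).
The exactly noiseless limit (every observation of a genotype identical) is
degenerate for REML and is computed directly: all variance genotypic.
`h2_spectrum()` applies this per wavelength, treating reflectance at each
wavelength as an individual trait. On balanced simulated trials
(200 genotypes x 2 environments x 2 replicates, sigma^2_g = 2,
sigma^2_ge = 1, sigma^2_eps = 2, generative H^2 = 2/3) the mean estimate
across 20 seeds is within 0.05 of 2/3.

## Cross-dataset transferability and sensitivity

`transfer_matrix()` fits, for every ordered (train, test) dataset pair and
trait, a PLSR model (NIPALS regression mode via mixOmics, 30 latent
variables, column mean-centering only — no unit-variance scaling) on the
full training dataset and scores it on the full test dataset. There is
deliberately no within-dataset split: the protocol is cross-dataset, so the
diagonal is training-set performance and is labelled as such. Scores are
Pearson `r`, the coefficient of determination `R^2` computed on the test
values, and a clamped copy `max(R^2, -1)` for display. The requested 30
components are capped at `min(n - 1, n_wavelengths)` with a warning.

`sensitivity_profiles()` implements one-at-a-time sensitivity: each sample
is simulated with one trait at its actual value and the other five at the
dataset means; the per-wavelength coefficient of variation `sigma/mu` of the
resulting ensemble measures how much spectrum that trait alone moves. CV is
`NA` where the ensemble mean is zero.

## The neural surrogate and integrated gradients

`train_surrogate()` trains a feed-forward network — four ReLU hidden layers
of widths 512, 256, 128, 64; linear output — to map a reflectance spectrum
to one trait (or several, `train_multi_target()`). Training is
mean-squared-error descent with adaptive moments and decoupled L2 weight
decay, batch size 128, 500 epochs by default, and a step scheduler that
multiplies the learning rate by 0.95 every 10 *epochs*: a per-batch decay of
0.95 would annihilate the learning rate within a few epochs, so the epoch
reading is the only workable one. Per-trait defaults: learning rate 5e-4
(N, CHL, EWT, LMA) or 1e-3 (CAR, ANT); weight decay 1e-3 (N, CHL, EWT),
5e-3 (LMA), 5e-5 (CAR), 1e-5 (ANT). Inputs are raw reflectance fractions
and targets raw trait units; no standardization on either side (the
per-trait learning rates implicitly compensate for scale). The training
loop is compiled code (RcppArmadillo) driven by R's RNG, so `set.seed`
reproduces training bit-for-bit. `ensemble_train_predict()` trains members
with consecutive seeds and reports the ensemble mean and across-model
dispersion, dropping diverged members as long as at least half survive.

`integrated_gradients_profile()` attributes a prediction to wavelengths via
the path integral from a baseline; the baseline defaults to the all-zeros
spectrum — the natural origin of reflectance space, which also makes the
linear-model attribution exact. The completeness identity
`sum IG = F(x) - F(baseline)` is recorded per sample as a residual; at 512
steps it is below 1% of the mean prediction for trained models. On inputs
corrupted with band-localized noise, a surrogate for a broad-band trait
places markedly lower mean absolute attribution inside the noisy bands than
outside (ratios around 0.03-0.15 in the test configurations) — the
mechanism by which surrogate inversion stays transferable despite noisy
wavebands.

## The synthetic-data generator

Everything above is testable offline because `synthio` builds all inputs:

* `synthetic_optical_constants()` — Gaussian-sum absorption bands per
  constituent on a smooth refractive-index curve (base 1.4). The default
  layout nests the carotenoid (500 nm) and anthocyanin (550 nm) bands inside
  the chlorophyll band support (480/670 nm) — the pigment-masking
  configuration that makes CAR and ANT weakly identifiable — and gives water
  (1450/1940/2400 nm) and dry matter (1720/2100/2300 nm) broad bands in the
  long-wavelength half. These synthetic constants stand in for unpublished
  calibration spectra; externally calibrated tables load through
  `read_optical_constants()` in the same format.
* `sample_trait_population()` — seeded draws with truncated-normal,
  log-normal (long-tailed) and two-component-mixture (bimodal) marginals and
  a Gaussian-copula rank correlation between CHL and CAR. Three archetypes:
  `wide` (broad species-diverse coverage, long-tailed CAR/ANT, CHL-CAR rank
  correlation 0.8), `crop` (narrow unimodal, correlation 0.5) and
  `tropical` (bimodal marginals confined to a shifted region, correlation
  0.6). The tropical archetype is deliberately *narrow* bimodal: its modes
  must not span the wide archetype's range, otherwise a linear model trained
  on it interpolates the extremes and transfers well, which is not what a
  single-species canopy dataset does.
* `corrupt_to_measured()` — additive noise (sd 0.04) plus multiplicative
  jitter (sd 0.3) inside the four canonical low-reflectance problem bands
  (400-500, 600-725, 1860-2025, 2325-2450 nm), background sd 0.001 outside,
  clipped to [0, 1]. The magnitudes are free parameters chosen once so that
  the four bands are reliably recovered by `flag_low_accuracy_bands()` at
  n = 50 while out-of-band correlation stays above 0.97; no quantitative
  noise model exists to calibrate against.
* `simulate_population_trial()` — genotype / environment / GxE / residual
  effects at stated variances injected on one trait axis (default CHL) and
  propagated through the forward model, with optionally unbalanced
  replicate (1-2) and repeat (1-3) counts. The default base population is
  degenerate (all traits point-mass) so that the injected effects are the
  only genotypic variance and the generative H^2 is recoverable at
  trait-sensitive wavelengths; a non-degenerate base population is available
  but adds genotypic variance at every wavelength.

Sub-streams are derived from the user seed per operation
(operation name + seed), so cross-module pipelines are reproducible without
global state.

What the generator does *not* emulate: instrument spectral response
functions, radiometric calibration chains, scattering-model misspecification
(the same plate model generates and inverts the spectra), or real trait
covariance beyond the CHL-CAR pair. Passing tests therefore demonstrate the
internal consistency and the claimed orderings of the framework, not
agreement with any particular spectrometer.

## Study sizes and design choices in the checks

The default desk grid is 51 points over 400-2450 nm (the full 1-nm grid with
2051 points is available via `wavelength_grid()`); all bundled checks run on
the desk grid. Sizes used: 50 samples for the regeneration cycle, 100 draws
for inversion recovery, 1000 draws for the energy budget, 20 trials of
200 x 2 x 2 for heritability, 250 samples per archetype for the transfer
matrix, 2000/500 train/test samples and 200 epochs for the surrogate, and a
10-model ensemble.

Two design points deserve emphasis:

* **Transfer orderings are group comparisons.** On every cross-dataset pair
  the mean R^2 of the four broad-band traits is compared with the mean R^2
  of the two masked pigments. Per-trait orderings are not stable: whenever a
  narrow training set meets an out-of-domain test set, some trait's linear
  model extrapolates to arbitrarily negative R^2 (this is why transfer
  displays clamp R^2 at -1), and the ordering between two such explosions is
  numerical noise. The group means are robust because the masked pigments'
  failures are systematically larger.
* **30 PLSR components on a 51-point grid is nearly saturated regression.**
  On the full 2051-point grid 30 components is a small fraction of the
  space; on the desk grid it is most of it, which makes narrow-trained
  models more explosive out of domain than they would be at full scale. The
  group-mean comparison absorbs this; users working at full resolution can
  expect tamer off-domain behaviour.

## Known limitations

* The synthetic optical constants are qualitative stand-ins; no numeric
  agreement with any published coefficient table is asserted or implied.
* Inversion is reflectance-only by design; joint reflectance+transmittance
  inversion and Bayesian/posterior inversion are out of scope.
* The surrogate is a fixed architecture; no hyperparameter search is
  automated (the defaults encode a previously selected manual grid).
* Heritability is broad-sense, entry-mean only: no narrow-sense, marker or
  spatial-trend modelling.
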