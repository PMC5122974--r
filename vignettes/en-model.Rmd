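---
title: "The excitation-normalization model of cortical orientation maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The excitation-normalization model of cortical orientation maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pinwheelEN` simulates how a single, spatially uniform set of cortical
computations produces different visual physiology inside iso-orientation
domains and near pinwheel centres of the orientation-preference map. This
vignette records the model, its assumptions, the calibrations, the synthetic
data generators, and the numerical and design decisions a maintainer would
want to know about. It states no empirical result that the test suite and
the acceptance script do not themselves compute.

## The model

The model is a steady-state rate model: stimuli are static luminance images
and every stage maps its input to a scalar firing-rate-like response. No
temporal dynamics (flash timing, adaptation, synaptic depression) are
simulated; the equations contain none.

**Feedforward pathway.** A stimulus `S(x, y)` with luminance in [0, 1] is
passed through a pointwise Naka-Rushton photoreceptor,
`P = S^q / (S^q + L50^q)`, convolved with ON- and OFF-centre
difference-of-Gaussians kernels (`sigma_1 = sigma_2 / 3`), summed by a
push-pull simple cell (rectified ON inputs along a column at `x1`, rectified
OFF inputs along a parallel column at `x2`, half a grating period away), and
squared: `C = A * max(T_tot, 0)^2`.

**Cortical stage.** Each model neuron sits in a local neighbourhood of six
neurons at +/-100, 200, 300 micrometres whose preferred orientations are
read from the map (or from canonical iso/pinwheel templates). Surround
excitation multiplies the feedforward response by the Gaussian-weighted pool
(`sigma` = 180 um, weights sum to 1, self excluded):
`C_E = C * sum_j w_j C_j`. The excited response is then self-normalized with
a hyperbolic ratio whose semi-saturation term is the output `C_U` of a
non-oriented inhibitory neuron:
`C_EN = r_max * C_E / (beta1 * C_E + beta2 * C_U + beta0)`. The comparison
circuit replaces excitation-plus-normalization by division through the same
pool: `C_N = C / (sum_j w_j C_j + floor)`.

The central contract, asserted by construction in `simulate_population()`,
is uniformity: one global parameter set at every site. All regional
differences arise from the local distribution of preferred orientations.

## Parameters, defaults and calibrations

| parameter | default | units | rationale |
|---|---|---|---|
| grid | 96 x 96 px, 0.1 deg/px | — | resolves the DoG centre (3 px per sigma_1) and holds ~5 cycles of the default grating |
| spatial frequency | 0.5 | cyc/deg | typical cat area-17 optimum; resolvable by the DoG kernels |
| photoreceptor `L50` | 0.5 | luminance | the adaptation point: battery stimuli modulate symmetrically about mid-grey |
| photoreceptor exponent `q` | 3 | — | see below |
| DoG `sigma_2` (`sigma_1 = sigma_2/3`) | 0.9 (0.3) | deg | centre matched to the subunit spacing |
| subunits: narrow / broad | 8 / 2 | — | more subunits lengthen the column and narrow tuning; these produce half-widths of roughly 18 and 48 degrees |
| column offset | 1 | deg | half the default grating period (phase-opponent flank) |
| column placement | +0.25 deg shift | deg | an eighth period off-centre, so the unit responds at two of the four battery phases rather than one |
| spiking exponent `m` | 2 | — | within the measured range for simple cells |
| spiking gain `A` | calibrated | — | best single-phase response of the narrow unit to the preferred full-contrast grating is 1 |
| neighbourhood sigma | 180 | um | matches the homogeneity-index Gaussian |
| `beta0` | 0.01 | response units | keeps the EN denominator above zero |
| `beta1`, `beta2` | 1 | — | left at 1 for all predictions |
| `C_U` semi-saturation | calibrated | drive units | the pooled thalamic drive at the lowest battery contrast (1/64), making the cell "severely compressed": its response at 25% contrast is at least 80% of its full-contrast response |
| `C_U` gain | calibrated | — | `beta2 * C_U` at full contrast equals 2x the iso-domain peak `C_E` (`normalization_strength = 2`) |
| DN floor | 0.1 | response units | see below |

**Photoreceptor exponent.** The transduction must compress the grating
fundamental as contrast grows; this is the model's source of pre-cortical
cross-orientation suppression. A hyperbolic form with the semi-saturation at
or below the mean luminance does the opposite — the dark half-cycle has ever
higher gain, and the contrast response turns expansive (we verified this
numerically for `L50` from 0.08 to 0.5 at exponent 1: the orthogonal-plaid
"suppression" index comes out at -0.25 to -2.3, i.e. facilitation). A
sigmoid inflected at the operating point (`L50 = 0.5`, `q = 3`) compresses
both half-cycles symmetrically; it gives the feedforward pathway an
effective semi-saturation contrast near 0.54 and a positive suppression
index, while leaving enough low-contrast response for summation in the
contrast-mixture experiment. `q` is exposed and can be set to 1 to recover
the purely compressive regime.

**Push-pull composition.** `pushpull_geometry()` has a `pull_weight`
argument: 0 (the default) sums the two rectified columns; 1 subtracts the
opposite-polarity rectified input at each sample (classic antiphase
inhibition), which removes the untuned response pedestal entirely. The
default keeps the pedestal because it is functionally meaningful here: it is
what makes plaid responses exceed component responses at matched low
contrasts (the summation regime) while the photoreceptor compression still
produces net suppression at higher contrasts.

**Normalization strength.** The `C_U` gain controls where the EN
denominator sits relative to `C_E`. If `beta2 * C_U` is small compared with
the peak `C_E` (saturation ratio near 1), the normalization flattens the top
of the tuning curve and iso-domain tuning *broadens*; with
`normalization_strength = 2` the peak is only mildly saturated, the tuned
pool's flank suppression dominates, and iso tuning narrows while the
contrast response still bends visibly more in iso domains than at pinwheels.

**DN floor.** With a floor that is negligible against the pool (for example
`beta0 = 0.01`), dividing an iso-domain cell by its co-tuned surround
cancels the tuning entirely (the ratio curve is flat to within a few
percent) and a tuning width is undefined. The comparison model is meant to
broaden, not erase, iso-domain tuning, so its floor defaults to 0.1 on the
calibrated response scale — comparable to the pool response at non-preferred
orientations. `dn_response()` exposes the floor as an argument.

**Pinwheel neighbourhood template.** `canonical_neighborhood("pinwheel")`
rotates preference linearly along the track (90 degrees per 350 um, i.e.
+/-26, 51, 77 degrees at +/-100-300 um). Six preferences spaced *evenly*
over 180 degrees would be invariant under a 90-degree shift, making the
excitation pool exactly non-oriented; no tuning broadening can then occur.
A rotating track matches the geometry of a penetration passing near a
pinwheel centre and yields the anti-tuned pool that drives broadening.

**Neighbour pools use the narrow class.** The uniform-cortex contract means
the pool is always built from the canonical (narrow) units; `tuning_class`
selects only the reference unit's thalamic input geometry. Broad-reference
units with broad-class pools show no broadening, because broad tuning
smooths the pool flat.

## Stimuli and response conventions

Gratings follow
`S = 0.5 + 0.5 * c * sin(2 pi f (x cos theta + y sin theta) + phase)`;
plaids sum component modulations about mid-grey, and the total contrast
(sum of component contrasts) may not exceed 1 — except in the
contrast-mixture experiment (`run_contrast_mixture()`), where a 25% mask plus a test of
up to 100% is rendered with explicit luminance clipping to [0, 1] (monitor
saturation). Battery structure: 8 orientations x 4 phases x 7 octave
contrasts for gratings; all orientation pairs and all 16 phase combinations
for 50%/50% plaids; 1/2/4/8 equally spaced components at total contrast 1
for the complexity series (so per-component contrast falls as 1/n); the
octotropic plaid is the 8-component case. Responses are always averaged
over phase variants, mirroring flashed presentation: a common phase offset
for gratings and multi-component plaids, all phase combinations for pairs.

Because the DoG kernel is isotropic, the response of a unit preferring
`theta` to stimulus `S` equals the response of the vertical-preferring unit
to `S` rotated by `-theta`; the implementation rotates the column sampling
geometry instead, so one convolution per stimulus image serves every
preferred orientation. This is exact, not an approximation.

## Tuning-width conventions

Two half-width-at-half-height measures coexist deliberately:

* `fit_von_mises()` + `hwhh_from_kappa()` — the recording-analysis measure:
  a Von Mises fit with a free baseline, HWHH of the fitted curve above its
  baseline (closed form `0.5 * acos(1 - log(2)/kappa)`). Used for synthetic
  recordings and the population pipeline, as in the experimental protocol.
* `hwhh_direct()` — for noiseless, finely sampled model curves: half height
  above the curve minimum, located by linear interpolation, sides averaged.
  The Von Mises baseline parameter absorbs exactly the flank suppression
  that constitutes EN sharpening, so fitting a parametric shape to model
  predictions obscures what the curves plainly show.

`run_model_comparison()` samples model tuning every 7.5 degrees (model
predictions are not limited by the 8-orientation recording battery) and
reports both measures (`hwhh`, `hwhh_vm`).

## Synthetic data: what it emulates, what it does not

`generate_map()` band-pass filters complex Gaussian noise at the map's
characteristic frequency (wavelength 1000 um, pixel pitch 20 um, relative
bandwidth 1/3) and halves the argument. This reproduces the features the
analyses rely on — a quasi-periodic mosaic with phase singularities of
charge +/-1/2, a uniform orientation distribution, and a full dynamic range
of local homogeneity — but not the geometric regularities of measured maps
(anisotropies, ocular-dominance coupling, vasculature artefacts). Passing
the map-based tests therefore says nothing about those properties.

`synth_recording()` draws Poisson spike counts around separable
Naka-Rushton-times-Von-Mises means. Real multi-unit activity is
over-dispersed relative to Poisson, correlated across sites and trials, and
its "response magnitude" is an area under a smoothed PSTH rather than a
trial-mean count; parameter-recovery results here bound estimation error
under ideal noise only. Baseline firing defaults to 0 and is configurable.

The electrode-track emulation uses exactly 100 um site spacing,
angle-doubled bilinear interpolation of the map, a signal-to-noise filter
(mean preferred response at full contrast over the s.d. at the least
preferred orientation and lowest contrast, threshold 5), and the rule that a
1D homogeneity index needs at least three valid sites on each side.

## Numerical choices

* Convolutions are FFT-based with reflective padding; reflective boundaries
  avoid spurious edge responses on small grids. The DoG kernel extends to 3
  surround s.d. and each Gaussian is normalized to unit discrete volume, so
  the kernel sums to zero and blank screens evoke exactly nothing.
* Naka-Rushton fits use bounded Levenberg-Marquardt with 10 starts
  (5 log-spaced `c50` values x 2 exponents); exponents are bounded to
  [0.2, 8]. Fit quality is the Pearson correlation between fit and data;
  fits below 0.95 are flagged, never silently dropped.
* Von Mises fits are solved by profiling: for fixed (kappa, theta_p) the
  model is linear in (baseline, amplitude), so a coarse grid scan is refined
  by Nelder-Mead on the profiled residual and then polished with
  Levenberg-Marquardt, keeping whichever solution has the lower residual.
  This recovers noiseless parameters to ~1e-7 and never fails on flat-ish
  curves (plain multi-start nonlinear least squares intermittently aborts
  with singular gradients on exactly symmetric data). Flat data short-circuit
  to circular variance 1 with an undefined (NA) half-width.
* The nonlinearity index integrates curve-minus-chord by the trapezoidal
  rule (1000 intervals by default) between the effective semi-saturation and
  contrast 1, normalized by `(1 - c50_eff) * R_max_eff / 4`; a
  semi-saturation at full contrast degenerates the construction and returns
  NA with a warning.
* The map uniformity check in the tests subsamples pixels at half-wavelength
  spacing before the chi-square: neighbouring pixels are strongly
  correlated, so a pixel-level test has a wildly inflated effective N.
* Problem sizes in the tests and population runs: a 256 x 256 map for the
  120-neuron population (40 per homogeneity stratum), a 512 x 512 map and
  500 sample points for the 1D/2D homogeneity comparison, 100 synthetic
  sites at 20 trials for parameter recovery. These give stable statistics at
  interactive runtimes.
* Multiple-testing correction is not applied anywhere; raw p-values are
  reported.

## Known limitations

* The complexity-series *enhancement* at pinwheels — broad pinwheel units
  responding relatively better to 4- and 8-component plaids under EN than
  their thalamic input does — is not reproduced by this implementation under
  any parameter setting we explored. Structurally, `C_E = C * pool` with the
  pool responding better to a full-contrast preferred grating than to
  1/8-contrast plaid components puts pinwheel-broad units in the linear
  normalization regime, where the relative complex-plaid response can only
  fall. The octotropic *regional ordering* (pinwheel > iso, and its negative
  correlation with homogeneity across a population) does hold and is what
  the tests assert; the complexity series is reported as a diagnostic in
  `run_model_comparison()`, not asserted.
* The mean 1D homogeneity index over eight penetration angles exceeds the 2D
  index at a sizeable fraction of locations (reported by `lhi_compare()` as
  `frac_excess_gt_0.2`); a line sample simply sees less orientation variety
  than a disc. The two indices remain strongly monotonically related, which
  is what track-based classification needs.
* Absolute response scales differ between tuning classes (a broad unit's
  drive is roughly 16x weaker than a narrow unit's); comparisons across
  classes are therefore made in relative terms throughout (responses
  normalized to each unit's own preferred-grating response).
* The command-line entry point is intentionally absent: the package's
  functions, the test suite and `scripts/acceptance.R` are the interface; an
  analysis session in R is the expected usage.
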