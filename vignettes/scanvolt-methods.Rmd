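---
title: "Models and methods behind scanvolt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scanvolt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scanvolt)
```

`scanvolt` models camera-based scanless two-photon voltage imaging: a
soma-sized (12–17 µm FWHM), temporally focused spot excites a
negative-going, membrane-targeted voltage indicator, and an sCMOS camera
records the fluorescence at 100–1000 Hz. This vignette documents the
models, their assumptions, the parameters that matter, and the design
choices made where the problem was genuinely open. It states no result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The synthetic-recording forward model

`render_movie()` computes, for every pixel and frame,

```
E[counts] = background + F0_px · rel_F(t) · bleach(t) · gate(t)
counts ~ Poisson(E[counts]),   16-bit clipped
```

* **Geometry.** A cell is a membrane annulus (default width 1 µm) at the
  soma radius (default diameter 12 µm, matching the spot so the membrane
  is illuminated), with the interior at 15 % of the membrane brightness.
  Each cell is gated by a top-hat illumination disc of the spot FWHM
  centred on its soma. Coordinates are (x, y) in µm from the field
  corner; pixel indices are 1-based (R convention), with pixel centres at
  (i − 0.5)·`pixel_size`.
* **Voltage response.** `rel_F = 1 − s·ΔV/100 mV`, convolved with a
  unit-area bi-exponential kernel (rise 1 ms, decay 2 ms by default).
  The linearised response with s = 0.43 reproduces the characterised
  −43 %ΔF/F₀ per 100 mV; the F–V curve of the real indicator is measured
  but not parameterised in the source characterisation, so the linear
  form is the default and the kernel is configurable. The defaults are
  deliberately fast placeholders — fast enough that a 3 ms AP-like pulse
  reaches near-steady amplitude. Where a comparison depends on the
  indicator's true off-kinetics (the 125 Hz-train rate comparison below),
  the tests pass a 5 ms decay explicitly, the published order of
  magnitude for this indicator family.
* **Two-photon scaling.** `F0_px` scales with the *square* of the power
  density relative to `reference_power_density` (default 0.88 mW µm⁻²,
  the 100 mW-per-12-µm-cell condition; the per-target power convention is
  `power_density × π(FWHM/2)²`, which maps 0.88 → 100 mW and
  0.66 → 75 mW).
* **Photobleaching.** Single exponential towards a floor of 0.70 with
  the time constant calibrated so 3 s of continuous illumination at the
  reference power leaves 0.80 of the initial fluorescence; the rate
  scales linearly with power ratio. In the dark, fluorescence recovers
  towards 0.985 of the pre-epoch value with a time constant set so a
  2.5 s gap restores 0.97. The 0.80/0.97 pair is the generator's ground
  truth for the photostability and photorecovery metrics.
* **Randomness.** One master seed; scene placement, spike times, speckle
  and shot noise draw from named sub-streams, so movies are bit-identical
  per (config, seed).
* **Protocols.** `make_protocol(1..5)` reproduces the characterisation
  timings: three 100 ms/100 mV steps under 3 s continuous illumination;
  the same steps under 200 ms strobed illumination 2.5 s apart; ten 3 ms
  pulses at 20 Hz in a 500 ms window; six 20 ms sub-threshold steps,
  0–2.5 mV in 0.5 mV increments; and 30 s of random (Poisson, ≥20 ms
  refractory, default 0.9 Hz) AP-like events. Waveforms are sampled at
  10 kHz, emulating the electrophysiology digitiser.

**What the generator does not emulate:** speckle statistics of real
holographic phase masks (only an optional log-normal static gain),
neuropil and out-of-focus crosstalk structure, movement (QC tests inject
rigid shifts explicitly), dark/read noise, and the indicator's true F–V
nonlinearity. Tests passing on synthetic data therefore demonstrate the
*analysis* is correct under the stated forward model, not that the model
captures every property of real tissue.

## 2. Trace extraction

`pixel_weights()` regresses each pixel in the segmented region on the
mean trace of that region (ordinary least squares with intercept — the
simplest reading of regression-based weighting); weights are the
non-negative slopes renormalised to sum to one, and the support excludes
non-positive slopes, so it always shrinks within the segmentation. On an
ROI that mixes responsive and non-responsive pixels this weighting can
only increase the −%ΔF/F₀ step amplitude relative to the unweighted mean
(slopes are proportional to per-pixel amplitude), which the tests assert
as an inequality.

`initial_segment()` scores pixels by correlation with the ROI-mean trace
and keeps those above half the 99th-percentile score, floored at 4/√T
(chance level); an ROI with no pixel above chance raises "no responsive
cell". Manual sub-region hints split overlapping cells.

`detrend_trace()` removes the multiplicative bleach trend with a robust
bi-exponential-plus-offset fit (a single exponential seeds it and stands
in when the richer fit fails; a running 20th-percentile baseline over a
1 s window is the fallback, with a warning). Robustness is an iterated
down-weighting of strongly negative residuals so the negative-going
transients are not absorbed — step amplitudes are preserved to better
than 2 % on traces bleached to 0.80. Baseline windows default to the
first 10 % of each illumination epoch. SNR is signal amplitude divided by
the baseline standard deviation, on the −%ΔF/F₀ scale; the SNR-vs-power
linearity test removes the within-epoch (power-dependent) bleach slope
from the baseline before measuring noise, without which the deterministic
trend masks the shot-noise scaling.

`correlation_fwhm()` radially averages the correlation image about the
positive-weighted centroid and interpolates the half-maximum crossing
linearly. `sbr()` is the amplitude of the weighted in-support trace over
the amplitude of the mean background trace (amplitudes as
|mean(signal window) − mean(baseline window)|); the definition is
recorded in the output, and a fluctuation-free background caps the ratio
with a flag.

## 3. Spike detection and evaluation

`detect_spikes()`: (1) candidate peaks of the −%ΔF/F₀ trace above 3σ
(noise σ from iteratively trimmed first differences — mad(diff)/√2 —
robust to event-laden traces); (2) the template is the mean waveform of
the most prominent peaks (top decile, at least five) in a 20 ms window,
peak-normalised; prominence is height above a low (20 %) quantile of a
±100 ms neighbourhood, which stays honest inside dense trains; (3) events
are kept when their amplitude exceeds `snr_threshold` (default 5, the
working threshold of the characterised recordings) times σ *and* their
central waveform correlates with the template at ≥ 0.5. The correlation
gate uses the central half of the window because the template's edges
carry neighbouring-event bumps in dense trains, which would otherwise
penalise the first and last spikes of a train. A 4 ms refractory floor
merges doubles (the larger wins).

`match_events()` pairs detected and true events one-to-one within ±5 ms
(a 500 Hz frame period plus jitter; configurable). The closest-pair
greedy is augmented by an earliest-available sweep over the sorted lists,
which is provably maximum-cardinality for this interval structure, so the
counts always equal the optimal assignment (asserted against an
augmenting-path oracle in the tests). TN ≡ 0, and precision, recall and
F1 follow the standard formulas, with zero-denominator cases raised as
errors rather than silently returned as 0.

`detection_probability_curve()` simulates photon-budget-matched trains
(total photons per second fixed, so frames at 1 kHz carry half the
photons of 500 Hz), detects, and calibrates out the fixed sensor lag (the
fluorescence peak trails the AP onset by the kinetics plus exposure
binning) before matching. With 5 ms decay kinetics this reproduces the
characterised behaviour: ≥95 % detection of 100 Hz trains at 500 Hz, and
a clear advantage of 1 kHz over 500 Hz for 125 Hz trains.

`trial_average()` forms cumulative means over repeats; baseline noise
scales as n^−1/2 and, under the sub-threshold protocol's photon budget,
25 repeats lift a 1 mV step above SNR 1.

## 4. Light-induced heating

The temperature rise obeys the heat equation in a homogeneous, isotropic
medium and is evaluated by quadrature of its Green's function:

```
ΔT(r,t) = (1/ρc) ∫₀ᵗ ∫ Q(r′) (4πD(t−t′))^(−3/2) exp(−|r−r′|²/4D(t−t′)) dr′ dt′
```

* **The heat source is the whole illuminated column, not the focal
  spot.** Two-photon *signal* is confined to ~9 µm axially, but heating
  is one-photon absorption of the propagating beam: a soma-sized, low-NA
  spot has a Rayleigh range of ~0.4 mm, so `absorbed_source_field()`
  builds a Gaussian-beam column (waist σ from the lateral FWHM,
  divergence from the wavelength in water) absorbed along its full path
  with `q(z) = µ_a P(z)` per metre. A focal-only source would absorb
  microwatts and predict rises an order of magnitude below the ones this
  geometry reproduces. Energy bookkeeping closes by construction and is
  asserted to <0.1 %.
* **Quadrature.** Axial segments (0.5 µm near focus, geometric towards
  the bounds) contribute erf differences against the axial kernel; the
  lateral Gaussian convolves analytically (variances add); elapsed time
  is integrated on a log grid. The solution matches the steady
  point-source limit `P/(4πκr)` to <2 % and an explicit
  finite-difference solver of the cylindrical heat equation to <5 % (both
  in the tests).
* **Boundary.** The exposed sample surface is a perfect heat sink:
  `ΔT_bounded = ΔT_infinite(source) − ΔT_infinite(mirrored source)`,
  exactly zero on the plane and everywhere below the infinite-medium
  solution. The default focal depth is 300 µm below that surface, with
  the absorbing medium extending 4 mm.
* **Constants.** κ = 0.53 W m⁻¹ K⁻¹, ρ = 1090 kg m⁻³,
  c = 3650 J kg⁻¹ K⁻¹ (standard bioheat values for cortical tissue,
  D = κ/ρc ≈ 1.33 × 10⁻⁷ m² s⁻¹); scattering length 166 µm and
  anisotropy 0.9. The linear absorption coefficient at 1030 nm is the one
  genuinely free constant — published values run from ~17 m⁻¹ (pure
  water) to ~50–60 m⁻¹ (perfused grey matter). It is set **once** to
  µ_a = 40 m⁻¹, within that range, by requiring the single-target
  reference condition (12 µm spot, 75 mW, 30 s continuous) to reproduce
  the characterised ~4.5 K benchmark; every other heating quantity — the
  150 mW and 12.5 mW conditions, the 16 × 10 mW field-centre rise, the
  12.5 ms rise, and the targets-per-depth budget — is then a prediction
  with no further freedom, checked in the acceptance suite within a
  ±30 % band that reflects the bracketed constants.
* **Strobing and multi-target.** Linearity of the heat equation gives
  strobed responses as differences of step responses and multi-target
  scenes as superpositions. 15 ms pulses at 5 Hz leave a residual before
  each pulse below 10 % of the per-pulse peak (negligible inter-pulse
  cross-talk), and the 30 s field-centre rise of 16 randomly placed
  targets varies by <10 % (coefficient of variation) across placements.
* **Scattering.** Power compensation for depth is exposed under two
  conventions: the reference form `exp(ℓ_s/ℓ)` (the default, as used in
  the heating estimates this package reproduces) and the Beer–Lambert
  form `exp(ℓ/ℓ_s)`. The reference form *shrinks* with depth, so under it
  the admissible target count is not monotone in depth; the tests check
  monotonicity under Beer–Lambert and the 10–15-target consistency window
  at 150 µm under the default. With scattering enabled, ballistic power
  decays as `exp(−z/ℓ_s)` and the scattered remainder heats a halo that
  broadens as an angular random walk with anisotropy g.
* **Known limitation.** The model's rise is slower than its plateau
  suggests experimentally: at 12.5 ms the spot-centre rise is ~2.2 K
  against a characterised ~3 K (the source characterisation itself notes
  large model-vs-experiment rise-time differences). The value sits inside
  the ±30 % band but at its edge; the kernel is implemented as described,
  not corrected.
* **`bpm_scatter()`** is the optional wave-optics engine: split-step
  angular-spectrum propagation through Gaussian random phase screens with
  variance `Δz/ℓ_s` per screen (so ensemble ballistic power decays with
  ℓ_s, verified to 15 % over 40 seeds) and correlation length
  `√(2/(1−g))/k` (tying the per-event scattering angle to g). Free-space
  propagation matches the analytic Gaussian-beam envelope to 1 %.

## 5. Motion QC and pipeline

`motion_check()` smooths with a separable 3-D Gaussian (σ = 1 frame,
5 × 5 px), subtracts each frame's median (a scalar background, so the
camera offset does not drag the centre of mass towards the frame centre),
tracks the per-frame centre of mass, and rejects when
|cor(|ΔCoM|, |Δintensity|)| > 0.5 *and* the peak displacement exceeds
0.5 px — the displacement floor keeps static recordings with numerically
tiny wobble from being rejected. Sigma units are frames (t) and pixels
(x, y). QC only annotates; it never modifies data.

`run_pipeline()` chains simulate → QC → extract → detect → evaluate with
stage-tagged errors, a config hash in every output, and byte-identical
reruns under a fixed config.

## 6. Problem sizes and numerical settings

The test and acceptance runs use 32 × 32 px ROIs at 0.65 µm/px (a 4 × 4
binning of the native 0.1625 µm sensor pixels — the natural choice for
desk-scale synthetic work, and every algorithm is resolution-agnostic),
movies of 300–15 000 frames, 10–20 placement seeds for multi-target
averages, 40 seeds for the scattering ensemble, and a 100 ms
finite-difference cross-check on a 5–10 µm grid. Quadrature defaults
(300 log-spaced time nodes, 0.5 µm near-focus segments) put the
Green's-function solver within 1 % of its converged value for these
geometries.
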