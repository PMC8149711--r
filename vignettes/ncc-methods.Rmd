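---
title: "Models and methods behind ncckit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ncckit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

ncckit quantifies nanosensor chemical cytometry (NCC) recordings: cells
flowing over a near-infrared fluorescent single-walled carbon-nanotube
(SWNT) sensor array act as low-contrast ball lenses (photonic nanojets)
that make each cell visible as a bright focal spot, while the array's
fluorescence quench under the cell reports the cell's hydrogen-peroxide
efflux. The package covers the full quantification chain — equilibrium
sensor calibration, transport and binding kinetics with trace-to-
concentration inversion, a first-principles lensing forward model with
refractive-index (RI) inversion, the image-analysis pipeline, a
ground-truthed synthetic data generator, and population statistics — and
is organized as an analysis workflow: the numbered scripts under
`analysis/` narrate the study, and every computation they perform lives in
the package so it is testable in isolation.

# Sensor calibration

The fractional quench of the sensor at H2O2 concentration $c$ follows a
Hill-type adsorption isotherm,

$$R(c) \;=\; \alpha\,\frac{(c/K_D)^n}{(c/K_D)^n + 1} + \beta ,$$

with amplitude $\alpha$ (percent), offset $\beta$, dissociation constant
$K_D$ and cooperativity $n$. The published constants for the
(GT)$_{15}$-DNA-wrapped SWNT H2O2 sensor are $\alpha = 88.74$,
$\beta = 2.30$, $K_D = 0.00204$ M and $n = 0.317$
(`default_calibration()`); $n < 1$ is negative cooperativity and gives the
characteristic sub-linear log-concentration curve. Two conventions matter:

* **Sign.** The model is fitted to the quench *magnitude*
  $R = -100\,(I - I_0)/I_0$; the printed $\alpha, \beta$ only make sense
  on a positive 0–100 scale. Raw traces stay signed.
* **Conditioning.** A typical curve is 7 points over 6 decades, which is
  ill-conditioned for an unbounded 4-parameter fit. `fit_calibration()`
  therefore uses bounded Levenberg–Marquardt
  ($\alpha \in [0,200]$, $n \in (0,3]$, $K_D \in [10^{-9}, 10]$ M) with
  $K_D$ parameterized on a log scale, and defaults its start to
  $\alpha = \max R - \min R$, $\beta = \min R$, $K_D$ at the geometric mid
  concentration, $n = 0.5$.

`limit_of_detection()` inverts the model at the blank response plus three
blank standard deviations. The blank standard deviation is a property of
each instrument run and is a required input; the package reports the LOD
as a function of it (`analysis/01_calibration.R`) rather than asserting
any single value. The response time `response_time()` is the first time
the trace reaches 90% of its total drop; in the strong-quench limit it
reduces to $t_{90} = \ln 10 / k_s$.

# Efflux transport and sensor kinetics

A cell releasing $M$ moles of H2O2 instantaneously produces the
decaying heat-kernel field

$$C(r,t) = \frac{M}{(\sqrt{4\pi D t})^{3}}
  \exp\!\Big({-\frac{r^2}{4 D t} - K t}\Big),$$

with $D = 1.5\times10^{-5}$ cm$^2$/s. Two mutually inconsistent decay
constants circulate for cellular H2O2 — $K = 6.93\times10^{-4}$ s$^{-1}$
and the value implied by a 1 ms half-life, $\ln 2 / 10^{-3} = 693$
s$^{-1}$. Both are selectable (`diffusion_params(decay =)`), and the small
value is the default: at the ~10 ms transport timescale from cell to
sensor the large constant would extinguish the field entirely,
contradicting the observation of strong quench footprints.

Sensor occupancy follows reversible first-order binding. At constant
concentration the intensity is

$$I(t) = \frac{I_0}{k_s}\big(k_r + k_f\,c\,e^{-k_s t}\big),
\qquad k_s = k_r + k_f c,$$

and the pointwise inverse used on measured traces is

$$c(t) = \frac{1}{k_f}\,\frac{I_0}{I}
  \Big[k_r\Big(1 - \frac{I}{I_0}\Big) - \frac{1}{I_0}\frac{dI}{dt}\Big].$$

Only the ratio $k_r / k_f = K_D$ is fixed by equilibrium data. The default
$k_r = 4.3\times10^{-3}$ s$^{-1}$ comes from the observed ~9 min
low-concentration response time via $t_{90} \approx \ln 10 / k_s$, and
$k_f = k_r / K_D \approx 2.1$ M$^{-1}$s$^{-1}$; both are configurable.
The steady state of the binding model reproduces the calibration isotherm
with $n = 1$; the equilibrium fit uses $n = 0.317$, an inconsistency the
source data do not resolve. The inversion uses the 1:1 binding model as
stated; this is a consistency limitation to keep in mind when comparing
absolute concentrations across very different regimes.

**Derivative smoothing.** The inversion differentiates a noisy trace. With
a moving quadratic (Savitzky–Golay) window of $N$ frames, the slope noise
scales as $\sigma_y / (\Delta t\, N^{3/2})$; at the default acquisition
(single-pixel read noise, $\Delta t = 1.2$ s) a 21-frame window leaves
~200 µM of concentration noise per point, so the pipeline default is a
41-frame quadratic window — still a factor of four shorter than the
relaxation time $1/k_s$, so it does not bias the dynamics. Edge samples
are fitted with asymmetric windows rather than discarded. Negative
concentration estimates are clipped at zero and counted.

**Rate conversion.** The per-cell efflux rate is
$\text{rate} = C_\text{end} V / t_\text{window}$ with the reference
monocyte volume $V = (\pi/6)(20\,\mu m)^3 = 4.19\times10^{-15}$ m$^3$ and
the 10-min stopped-flow window. Which instant of $c(t)$ enters the
conversion is not prescribed by the source; the default is the
end-of-window value, estimated as the mean of the trailing 10% of the
window for noise robustness, with maximum and time-average selectable.

# Lensing forward model

The paper's commercial FDTD solver is replaced by two independent
first-principles methods that cross-validate each other:

* `mie_near_field()` — the exact Lorenz–Mie series for the external near
  field of a homogeneous dielectric sphere, with the unpolarized camera
  observable (the average over the two incident polarizations, which is
  exactly azimuth-independent). The series is truncated at
  $x + 4x^{1/3} + 2$ terms and refused above size parameter 150.
* `propagate_through_target()` — a scalar angular-spectrum split-step
  propagator through the target's 3D index map, covering spheroids and
  concentric-shell targets the series cannot. Evanescent cutoff plus
  lossless phase screens make each step unitary (energy conserved to
  numerical precision).

On spheres in the cell-relevant range the two solvers agree on
enhancement, FWHM and focal distance to within a few percent
(`analysis/02_optics.R`), well inside the 15% envelope the tests enforce.

**Focal convention.** Metrics are taken at the beam's best focus (the
on-axis intensity maximum), emulating the experimental z-stage focusing.
For low-contrast cell-sized spheres this focus lies several tens of
micrometers behind the cell — consistent with geometric optics
($f \approx n r / 2(n-1)$) — and the package reports its own focal
distances rather than adopting any external figure.

**Observables and inversion.** At fixed radius the focal enhancement
rises and the FWHM falls monotonically with index contrast, and both vary
with radius, so the map $(\text{radius}, n_\text{rel}) \to (\text{FWHM},
\text{enhancement})$ is invertible. `invert_lensing()` performs the joint
nearest-neighbor search in normalized metric space on a bilinearly refined
sweep grid; `estimate_ri()` answers the diameter-conditioned query. This
joint inversion is the calibrated generalization of a scalar
area-dilation factor: enhancement resolves the RI dependence that would
otherwise confound the spot-size-to-diameter mapping.

# Image analysis

Detection convolves a frame with a Laplacian-of-Gaussian kernel
($\sigma = 2.4$ µm by default, about the lensing FWHM/1.414), thresholds
the response (user-set per batch; a robust `median + 8 MAD` automatic
default), labels connected components and deduplicates centroids within
one cell diameter. Patches are normalized so the background annulus
outside the secondary Airy peak has mean 1; the annulus inner radius is
the second detected ring plus two pixels, falling back to 70% of the
patch radius.

**Shape.** At 0.7 µm/px the half-maximum contour of a narrow (high-RI)
lensing spot spans only ~2 pixels, and binary-mask ellipse statistics
carry no shape information there. The package therefore estimates the
in-plane stretch by a fit: at the true (eccentricity, orientation,
center) every raw pixel sample lies on a single one-dimensional radial
profile, so the intensity sequence ordered by de-stretched radius is
smooth, and the sum of squared successive differences of that ordering is
minimized over the stretch parameters. The classic half-max mask
statistics are still computed (`eccentricity_mask`, contour area).
Profile metrics are then measured on de-stretched radii, making the
reported FWHM the area-preserving circular-equivalent width, directly
comparable to sweeps computed on spheres. FWHM itself is measured from
the raw pixel samples by a local linear fit around the half-maximum
crossing (no interpolation bias) for spots wider than ~3 px, and from the
interpolated fine profile for narrower spots; the regime split depends
only on the spot scale so reference sweeps and measured cells always use
the same estimator. Enhancement comes from an even-polynomial apex fit.

**Sweep calibration.** The inversion sweep used by the pipeline
(`calibrated_sweep()`) is built *as measured*: every (radius, $n_{rel}$)
node is rendered at the scene's pixel size and measured with the very
analyzer chain applied to data, averaged over the two-point
Gauss–Legendre quadrature of the uniform subpixel-offset distribution.
Systematic pixel-level effects thus cancel between calibration and
measurement by construction. The contour-to-area dilation factor is
regressed on the same renders.

Two further measures keep the size estimate unbiased, which matters
because the spot width depends only weakly on radius, so a 0.01 µm FWHM
bias already moves the inferred area by several µm². First, the metrics
patch is the average of the first 12 frames (read noise down 3.5-fold);
the sensor quench accumulated over those frames is divided back out of
the enhancement using the cell's own smoothed trace (the lensing spot
dims proportionally to the local quench, and the quench footprint is flat
across the spot core). Second, a system-level diameter correction
curve (a lowess fit of true over measured diameter against log
enhancement) is regressed once per configuration by pushing reference
renders — spanning the realistic size, shape, index and efflux ranges —
through the complete noisy pipeline. This is the end-to-end
generalization of the dilation-factor idea, absorbing the residual noise-
and quench-induced estimator bias that a noiseless sweep cannot
represent.

**Traces.** The cell trace is the single camera pixel nearest the
centroid; the background is the mean of 16 pixels on a circle outside the
secondary peak (default radius 8 µm) after per-frame outlier removal at
median ± 3 MAD (the placement geometry and outlier rule are package
choices; the acquisition description leaves both open). The normalized
trace is their ratio, which cancels illumination drift exactly.

# Synthetic data generator

The generator is the package's test bench: it encodes the published
population statistics as sampling distributions and renders recordings
with the physical structure the analysis assumes.

* **Areas.** Non-activated (−PMA): equal-weight two-component normal
  mixture at 248/294 µm² with component σ 18, matching the published
  overall mean 271 / σ 29; activated (+PMA): normal 263 / σ 24.
* **Efflux rates.** The published σ exceeds the mean (330/344 and
  624/497 amol·cell⁻¹·min⁻¹), which no normal distribution can produce on
  a positive support; rates are drawn from a moment-matched lognormal
  truncated at 4000 amol/min (hyperactive outliers above 1000 amol/min
  are a real feature of the non-activated population).
* **Eccentricity and RI.** Truncated normals on [0, 0.95] and
  [1.33, 1.45]. The published RI σ (0.05–0.06) is wider than any
  distribution supported on a 0.12-wide physical interval can realize
  (the maximum possible is 0.06, attained only by a two-point mass), so
  the printed σ is used as the pre-truncation scale and the location is
  calibrated numerically so the *truncated mean* equals the printed mean;
  the realized σ is necessarily smaller (~0.034). The same calibration is
  applied to eccentricity, where the correction is negligible.
* **Scene.** 0.7 µm/px (≈720 sensor pixels under a 20 µm cell), 0.1 s
  frames by default; the study-scale runs use 500 frames of 1.2 s
  covering the same 10-min stopped-flow window. Background 2000 counts
  with Gaussian read noise σ 50 (Poisson shot noise optional): with the
  measured enhancement factor 9.43 this puts the nominal lensing peak
  near 19,000 counts, on the observed 16-bit image scale, while leaving
  headroom so the brightest (high-RI) cells stay below the 65,535-count
  ceiling — a background of 10⁴ counts would clip every nominal peak.
* **Rendering.** Parametric mode draws a Gaussian core with the measured
  FWHM (3.37 µm) and enhancement (9.43) plus a damped cosine Airy skirt
  whose radii scale with the cell diameter (first ring at 0.199 d,
  spacing 0.132 d, geometry taken from the Mie profile of the reference
  monocyte). Physical mode evaluates the Lorenz–Mie focal profile at the
  cell's own diameter and RI. The coherent plane-wave model overstates
  the modulation of the extended, partially coherent sensor-array source,
  so physical-mode intensities are compressed as $1 + (I-1)\,c$ with $c$
  anchored once so the reference monocyte reproduces the measured
  enhancement 9.43. Eccentricity enters as an area-preserving in-plane
  elliptical stretch.
* **Quenching.** Each cell's local concentration is held at the
  end-of-window value implied by its efflux rate; the sensor under the
  cell follows the binding kinetics at that concentration, and the
  lensing spot dims proportionally to the local quench. The footprint is
  a compact super-Gaussian (radius scale 6.5 µm) chosen so the background
  ring stays unquenched; the true coupling between quench fraction and
  footprint shape is not quantified by the source and this is a declared
  modeling choice. The long-time heat-kernel field would in reality
  spread millimeters in ten minutes; the localized-footprint picture
  matches the observed "immediate spot" quenching instead.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: cell motion and flow-phase streaking,
photobleaching, per-chirality spectral structure, non-uniform sensor
coating, optical crosstalk between neighboring cells, focus drift, and
any real difference between the rendered lensing model and live-cell
optics (nucleus/cytoplasm structure is only available through the
concentric-shell interface of the propagation solver, not the default
path).

# Population statistics

`summarize_population()` reports mean, sample SD, variance, median and
the kernel-density mode (Silverman bandwidth) per group, plus the
fraction of cells above the 1000 amol·cell⁻¹·min⁻¹ high-efflux
threshold. `compare_groups()` reports percent changes of means, variances
and high-efflux fractions with seeded bootstrap confidence intervals (no
hypothesis tests — none are reported by the source; CIs are more
informative here). `detect_bimodality()` compares 1- vs 2-component
Gaussian mixtures by BIC with a ΔBIC > 6 decision rule (strong evidence
on the Kass–Raftery scale). At the configured −PMA component separation
(46 µm² against component σ 18, n = 400) this rule detects the area
bimodality in roughly 80% of seeds — the separation sits near the
detection boundary of a ΔBIC-6 rule, which is worth knowing before
interpreting a single unimodal call on real data. `kde2d_grid()` gives
product-kernel 2D densities on a 128×128 grid spanning the data ± 3
kernel SD, normalized to integrate to 1.

# Problem sizes and tolerances

The study-scale runs used throughout the analysis scripts and the
acceptance machinery simulate 400 cells per group, rendered 16 cells per
256×256-pixel stack with 500 frames of 1.2 s (a 10-min window). Sweeps
for the lensing inversion cover radii 6.5–12 µm and index ratios
1.005–1.10, beyond the truncated population support on both sides so that
no cell is clamped to the grid edge. With these sizes the recovered group
means land within three standard errors of the generating values, the
per-cell measurement noise is ~10% for efflux rates, ~0.03 for
eccentricity, ~0.002–0.005 for RI, and ~20 µm² for projected area (the
latter dominated by the flat radius dependence of the spot width at the
RI extremes). Cells whose metrics fall outside the physical hull of the
sweep, whose patch clips the frame edge, or whose spot carries no
significant peak are QC-flagged and excluded from summaries with a
logged reason, never silently dropped.

# Known limitations

* The RI population σ cannot match the printed value on the physical
  support (see above); means are matched exactly.
* Scalar (not vector) beam propagation for spheroids; adequate at the
  low index contrasts of cells, as the cross-solver checks show, but not
  for high-contrast reference beads.
* The 1:1 binding inversion and the $n = 0.317$ equilibrium fit are
  mutually inconsistent conventions inherited from the source; absolute
  concentrations carry that systematic.
* Stationary (stopped-flow) cells only; no tracking of moving cells.
* The quench-to-lensing coupling is a proportional model flagged in the
  generator metadata.
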