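# ncckit — nanosensor chemical cytometry of single-cell H₂O₂ efflux

Nanosensor chemical cytometry (NCC) measures the hydrogen-peroxide efflux
of individual immune cells without any label: cells flow through a
microfluidic channel whose surfaces carry a near-infrared fluorescent
carbon-nanotube sensor array. Each cell acts as a low-contrast ball lens
(a photonic nanojet) that projects the array's emission into a bright
focal spot — revealing the cell's position, size, shape and refractive
index — while the H₂O₂ the cell releases during stopped flow quenches
the sensor fluorescence underneath it, reporting its efflux rate in
attomoles per cell per minute. ncckit implements the full quantification
chain for such recordings, for researchers building or evaluating
label-free single-cell chemical cytometry.

## The models at the core

**Sensor calibration.** The percent quench follows a Hill-type isotherm

    R(c) = α (c/K_D)^n / ((c/K_D)^n + 1) + β

with the published constants α = 88.74, β = 2.30, K_D = 0.00204 M,
n = 0.317 (negative cooperativity).

**Efflux kinetics.** A burst release produces a decaying heat-kernel
concentration field; the sensor responds through reversible first-order
binding, I(t) = I₀/k_s (k_r + k_f c e^(−k_s t)) with k_s = k_r + k_f c,
and a measured trace is inverted pointwise,

    c(t) = (1/k_f) (I₀/I) [ k_r (1 − I/I₀) − (1/I₀) dI/dt ],

then converted to a rate via the reference monocyte volume
(π/6)(20 µm)³ and the 10-minute measurement window.

**Cellular lensing.** An exact Lorenz–Mie near-field series (spheres) and
a scalar angular-spectrum split-step propagator (spheroids, shells)
cross-validate each other; focal-spot FWHM and enhancement factor vary
monotonically with cell radius and refractive-index contrast, so the
measured pair inverts jointly to (diameter, RI).

**Imaging and statistics.** Laplacian-of-Gaussian detection, Airy-aware
patch normalization, stretch-fit shape statistics, centroid/background
trace extraction, and population summaries with bootstrap group
comparisons, Gaussian-mixture bimodality calls and 2D kernel densities.

A ground-truthed synthetic generator (`sample_population()`,
`render_stack()`) encodes the published population statistics of
non-activated (−PMA) and activated (+PMA) human monocytes and renders
16-bit time-lapse stacks with the physical structure the analysis
assumes, so every stage is testable without any external data.

## Worked example

Simulate a small activated-monocyte population, render and analyze it
blind, and compare with ground truth:

```r
library(ncckit)

scene  <- scene_spec(frame_dim = c(180, 180), n_frames = 120,
                     frame_interval = 5, cells_per_stack = 8)
config <- run_config(seed = 3, groups = "+PMA", n_cells = 8, scene = scene,
                     sweep_radii_um = seq(7.5, 11, by = 0.7),
                     sweep_n_rels = c(1.012, 1.025, 1.04, 1.055, 1.07, 1.085),
                     calibration_stacks = 3)
res <- run_pipeline(config, progress = FALSE)
subset(res$summary, variable %in% c("rate_amol_min", "ri"),
       c(group, variable, n, mean, sd))
```

```
 group      variable n       mean           sd
  +PMA            ri 6   1.400371   0.02031735
  +PMA rate_amol_min 6 598.436172 331.73644456
```

Six of the eight rendered cells pass QC (the two others are dim low-index
cells whose lensing metrics fall outside the inversion sweep, flagged in
`res$table$qc` rather than silently dropped). For those six, the quench
traces invert to a mean efflux rate of 598 attomole/cell/min and the
lensing spots to a mean refractive index of 1.400, against ground-truth
means of 615.5 and 1.397 for the same six cells. At the study scale
(400 cells per group, `analysis/04_pipeline.R`) the recovered group means
land within three standard errors of the generating values.

The numbered scripts under `analysis/` walk the full study: calibration
(`01`), optics cross-validation (`02`), population simulation (`03`), the
end-to-end pipeline (`04`) and population cytometry (`05`). The methods
vignette (`vignettes/ncc-methods.Rmd`) documents every model, default and
design decision.

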