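---
title: "Models and methods behind mocar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mocar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mocar)
```

`mocar` analyses droplet-array cultivation experiments in which bacteria
grow in microliter droplets on a grid of hydrophilic spots and are
observed by time-lapse bright-field microscopy. This vignette is the
package's own account of the models it implements, the parameters that
matter, and the choices made where the design was genuinely open.

## The measurement

Light transmission through a droplet decreases as biomass accumulates, so
the mean gray level over a droplet is a growth proxy, like optical
density in a plate reader but imaged. Each droplet has its own field of
view; `extract_transmission()` averages the pixels of a *measurement
disk* of 0.9 spot radii (`shrink_factor`), excluding the rim because the
hydrophilic/hydrophobic boundary produces artifacts no growth model
describes. Whether the original instrument averaged the whole droplet or
a sub-region is not knowable from the data; the shrunk disk is this
package's default and is recorded in every ROI.

Each curve is normalized to its initial value
(`normalize_curve`, `baseline_frames = 1`), which cancels the
per-droplet illumination differences exactly and makes every curve start
at exactly 1 (floating-point division of a value by itself). The
**threshold growth time** is the first time the raw normalized curve
intersects 0.99. Two readings of "intersects" were possible — the first
frame below the level, or an interpolated crossing; threshold times are
conventionally reported at 0.01-h precision, which a 0.5-h cadence can
only deliver by interpolation, so `threshold_growth_time()` linearly
interpolates between the bracketing frames. Smoothing (a centered moving
median, window 3) is applied only inside `classify_growth()` and
`detect_rebound()`, never before thresholding.

`classify_growth()` adds a sustained-drop guard: a droplet only counts as
grown if the smoothed curve *ends* at least `min_final_drop = 0.05` below
1, so a single-frame dip below 0.99 that recovers is not growth. The
guard's value is a package choice; with frame noise of 2 gray levels on a
~200-level background, spurious sustained drops of 5% are effectively
impossible (the mean over ~64,000 disk pixels has a noise sd near 1e-5 of
the normalized scale).

`detect_rebound()` targets the post-peak brightening of sporulating
droplets: it takes the global minimum of the smoothed curve and requires
a subsequent rise of `min_rise = 0.05` that stays above
`minimum + min_rise/2` for at least `min_frames = 6` consecutive frames
(3 h at the default cadence); the onset reported is the time of the
minimum, which for the synthetic sporulation model coincides with the
population plateau.

## Occupancy design

Cell loading is Poisson with mean `lambda = concentration x volume`.
`occupancy_pmf()` evaluates the mass function in log space (via R's
`dpois`), so extreme loadings such as λ = 1000 are exact. The inverse
design problem — what λ gives a desired single-cell fraction — inverts
λe^−λ, which is unimodal with maximum e^−1 at λ = 1; both roots are
available (`branch = "low"` favours clonality at the cost of empties).
Bisection to a bracket of 1e−12 was chosen over faster solvers because
the problem is one-dimensional and robustness is worth more than
microseconds. Note that at λ = 0.25 the multicell tail P(K ≥ 2) is 2.65%
while P(K = 2) alone is 2.43%; both round loosely to "about 2%", and the
API exposes both rather than forcing either to 2.0%.

## The synthetic scene generator

The generator exists because real droplet micrographs are rarely
deposited; it produces ground-truthed stacks on which every downstream
operation can be validated. Its defaults describe the reference
experiment: a 4 × 6 array of 3.18-mm spots, 1-µl droplets, four loading
concentrations (10³, 10², 10, 1 cells/µl) with six droplets per
concentration, frames every 0.5 h for 72 h.

**Latent growth.** Each founding cell seeds one microcolony with initial
biomass `b0 = 1` (biomass is measured in cell-equivalents) that stays
dormant for a per-cell lognormal lag (mean 2 h, sd 1 h — dormancy-exit
heterogeneity) and then grows logistically against a *shared* droplet
carrying capacity:

db_i/dt = µ b_i (1 − Σ_j b_j / K),  µ = 0.7/h, K = 10⁶.

µ = 0.7/h is a ~1-h doubling time, typical of enteric bacteria in rich
medium at room-temperature-to-30 °C conditions; K = 10⁶ cells per 1-µl
droplet corresponds to ~10⁹ cells/ml at saturation. Integration is
classical RK4 with substeps of at most 0.05 h, additionally split at
every lag so activation is sharp; a safety clamp rescales the state onto
K in the (numerically negligible) event of overshoot. Once all colonies
are active their biomass *ratios* are constant (the logistic factor is
shared), a property the placement algorithm exploits.

**Optics.** The spot is drawn at `background_intensity = 200` (8-bit)
times a per-droplet illumination multiplier (sd 0.05), the outside at
`oil_intensity = 120`. A colony is a filled disk whose area is
proportional to its biomass — `area_per_biomass = 5e-6` mm², a ~5 µm²
cell footprint, monolayer-like expansion consistent with the
agar-plate-like growth pattern seen in droplets — and whose interior
multiplies transmission by exp(−`colony_absorbance`) with absorbance 2.3
(~10% interior transmission). Colony disks are anti-aliased and the
fractional pixel weights are rescaled so their sum equals the exact disk
area: the droplet mean is then smooth in time even while colonies are
sub-pixel, which is what makes interpolated threshold times meaningful.
Gaussian noise (sd 2 gray levels) is added and frames are quantized to
8 bits. Colonies are confined to the droplet; a disk reaching the
droplet or frame boundary is clipped with a warning (collected, never
silently dropped, by `run_pipeline`).

Two constants deserve emphasis: with this footprint and capacity the
1%-transmission detection level sits near 1.4 × 10⁴ cell-equivalents,
two orders of magnitude above the largest default inoculum. That
separation matters because curves are normalized to their *initial*
value: a droplet seeded with N₀ cells already starts partially covered,
so the effective detection biomass is N₀-shifted, and only when N₀ is
small against the detection level is the threshold time linear in
log₁₀ N₀ with slope −ln(10)/µ — the closed-form check the test suite
performs. A generator tuned to detect at ~10³ cells would (correctly)
show curvature at the top concentration.

**Sporulation rebound.** When `sporulation = TRUE`, once total biomass
first reaches 0.99 K the colony areas freeze (cell numbers stop
changing) and the per-pixel attenuation term 1 − transmission relaxes
linearly to (1 − `rebound_fraction`) of its peak over
`rebound_onset_delay = 6` h: shrinking spores lose scattering
cross-section roughly in proportion to their projected size. This makes
the observed transmission rise proportional to `rebound_fraction`
(≈ 0.3 gives a rise of ~0.1 on the normalized scale; 0.01 stays below
the 0.05 detection floor), and places the curve minimum at the plateau
time, which is why the detector reports the minimum as the onset.

**Colony placement.** Centers are confined to 80% of the spot radius
(avoiding rim effects). For single-digit-to-few-tens occupancies the
generator also targets a minimum pairwise separation so that colonies
remain spatially distinct until the droplet nears saturation, mirroring
the observation that microcolonies do not merge until the solution turns
cloudy. The required separation is computed per droplet from the realized
lags (worst pair at total biomass K/2, shares ∝ e^(−µ·lag), plus 10%
margin), then sought by rejection sampling of uniform configurations,
then greedy maximin, and finally — when geometry makes uniform placement
incompatible with distinctness, typically at 5–6 colonies — a randomly
rotated ring at the smallest radius achieving the target. Above 50 cells
placement is simply uniform; distinct-microcolony counting is not a
meaningful observable there.

**Determinism.** All randomness flows from one master seed through
labelled 31-bit sub-stream seeds (counts per group, lags/centers/noise
per droplet, illumination), so rendering a droplet subset, or re-running
a scene, is bit-identical to the full run; the RNG name
(Mersenne-Twister) is recorded in scene configs and pipeline manifests.

## Imaging

`locate_droplets(mode = "grid")` trusts the layout: each field of view is
centered on its spot. `mode = "detect"` thresholds a frame at its 75th
intensity percentile, keeps the largest 8-connected component (at least
5% of the frame, else a detection error naming the cause), and fits
center = centroid, radius = sqrt(area/π); it exists for stacks whose
geometry metadata is unreliable and agrees with grid mode to within 2 px
on clean frames. Connected components come from a run-based union-find
labeller with 8-connectivity (`label_components`), validated in the test
suite against an independent flood-fill oracle.

`count_microcolonies()` thresholds *relative to the median in-disk
intensity* (0.85 of it) rather than at an absolute gray level, so
per-droplet illumination does not bias segmentation, discards components
under 20 px, and returns count and centroids. Counting is performed at a
checkpoint frame (`microcolony_checkpoint`): the first frame at which
every colony has reached 10 × the area floor while no pair has merged.
Counting late would fail for an interesting reason: once colonies cover
most of the disk the median itself is colony-dark and a median-relative
threshold stops meaning "darker than background".

## Statistical summaries

`summarize_groups()` uses the linear-interpolation quantile convention
(R type 7) and Tukey box-plot whiskers (most extreme observations within
1.5 IQR of the quartiles), with values beyond the fences listed as
outliers; a group where nothing grew is a valid summary with
`n_grew = 0`, not an error — single-droplet growth at the most dilute
loading is an expected outcome, not a failure mode.

`fit_threshold_vs_log_inoculum()` regresses threshold time on
log₁₀(cells per droplet). "Linear in concentration" is ambiguous for
this design; exponential growth to a fixed detection level predicts
linearity in the *logarithm* of the inoculum, so the fit uses log₁₀ and
records that choice rather than asserting it as anyone's intent.

## What the generator does not emulate

No diffraction, meniscus lensing or other physical optics; no focus
drift, stage drift, or vignetting; no motility, chemotaxis, oxygen
gradients under the oil, or cross-droplet contamination; colony interiors
are optically uniform. Passing the test suite therefore demonstrates that
the analysis chain is correct *given* monotone Beer–Lambert-style
darkening and logistic growth — it does not certify accuracy on any
particular instrument, and all rendering constants are free parameters of
the generator, not claims about one.

## Problem sizes and numerical tolerances

The test suite exercises the reference 24-droplet, 145-frame scene at
full resolution (100 px/mm) once, and uses coarser 40-px/mm scenes with
shorter horizons for unit tests; the occupancy Monte-Carlo oracle uses
10⁷ draws, plan-level occupancy statistics 10⁴ replicates. Key
tolerances: pmf normalization 1e−9 under adaptive truncation
(tail < 1e−9); root-finder bracket 1e−12; RK4 vs closed-form exponential
within 1e−6 relative (the contract is 1%); threshold recovery within one
frame (0.5 h) for ≥95% of grown droplets under default noise; dense
(0.05-h) re-rendering agrees with interpolated coarse crossings within
0.1 h. Degenerate inputs are defined, not accidental: zero cells render a
blank droplet, `lag_sd = 0` is a deterministic lag, `lag_mean = 0` no
lag, `carrying_capacity = Inf` pure exponential growth, and absent
threshold times are `NA`, never sentinel numbers.
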