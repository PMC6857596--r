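---
title: "Quantifying cytoplasmic freezing: models, parameters and design choices"
author: "cytofreeze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cytoplasmic freezing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytofreeze)
```

## The problem

Starved fission yeast cells can enter a state in which all structures large
enough to resolve by light microscopy — lipid droplets, fragmented
mitochondria, vacuoles — stop moving, while molecules the size of GFP still
diffuse almost freely. Measuring that transition across thousands of dim,
heterogeneous cells requires statistics that are robust to absolute
intensity, to per-cell brightness differences, and to dying cells that take
up vital dye. This package implements the quantification stack for that
measurement: a per-cell temporal correlation statistic for droplet motion,
particle tracking with time-averaged mean-square-displacement (MSD)
analysis, FLIP depletion curves, and spherocylinder morphometry with
bootstrap and error-propagated uncertainties. Everything is exercised
against a synthetic scene generator with exact ground truth, so the
pipeline's properties can be verified without real data.

## The PCC mobility statistic

For one cell with pixel sets $a$ (time $t_2$) and $b$ (time $t_3$,
42 s later by default),

$$ r \;=\; \frac{\sum_i (a_i - \bar a)(b_i - \bar b)}
  {\sqrt{\sum_i (a_i - \bar a)^2 \; \sum_i (b_i - \bar b)^2}} . $$

$r = 1$ describes a completely static intensity distribution; any particle
displacement between the two time points decorrelates the images and lowers
$r$. The statistic reports *whether* there is motion, not its physical
nature — it is not a diffusion estimate, which is why the package also
carries an MSD module.

The statistic is computed on **droplet probability maps**, not raw
intensities. The chain is: log transform (`log(1 + I)`), subtraction of a
smooth background (Gaussian blur, $\sigma$ = 20 px by default), a
difference-of-Gaussians band-pass at the spot scale ($\sigma$ = 1.2 px,
matching a diffraction-limited ~300 nm particle at 0.1 µm/px), quantile
normalisation of the response, and a logistic squashing to $[0, 1]$. Each
pixel then approximates the probability of belonging to a droplet, and the
map is insensitive to global intensity scaling — the property the whole
equalisation exists for, since droplet dye brightness varies strongly
between cells and increases during acquisition. The logistic gain (8) and
offset (0.35) were calibrated once on synthetic fixtures such that a blank
frame maps below 0.5 and a rendered spot peak above 0.9; they are exposed
as arguments, not hidden constants.

Two design points deserve note:

* **Frame pair.** Acquisitions are triplets ($t_1, t_2, t_3$); the
  correlation uses $(t_2, t_3)$ because the droplet signal rises mainly
  between the first two frames, which would spuriously decorrelate
  $(t_1, t_2)$. The generator reproduces this drift (`intensity_drift`,
  default ×1.15 from frame 2 onward), and `run_pcc_scene(frames_used =
  c(1, 2))` is available for sensitivity analysis.
* **Population summary.** Per-cell values are summarised as the median per
  independent experiment and the mean of those medians; the 95% CI is the
  normal approximation `mean ± 1.96·SE` over the experiment medians, and is
  reported as unavailable with fewer than three experiments. This matches
  the convention of plotting the mean of per-culture medians, and shares
  its caveat: it can underestimate the variance of a median.

Cells are segmented from the phloxine channel: Otsu thresholding of the
preprocessed image yields outlines (live cells) and filled interiors (dead
cells); hole-filled interiors seed a region growing (`EBImage::propagate`)
out to the outline, which also separates touching cells. A cell is flagged
dead when its eroded-interior median intensity exceeds a two-class Otsu
split of the per-cell medians; the split is only trusted when the upper
class is at least 3× brighter than the lower, so an all-live population is
never split, and a fixed fallback threshold is used below five cells. Dead
cells stay in the output, flagged, and never receive a PCC or a trajectory.

## Tracking and time-averaged MSD

Detection is a difference-of-Gaussians local-maximum finder with
sub-pixel centroid refinement, emulating a Mosaic-style tracker with
radius 4 px. The percentile-based intensity cutoff of that tracker is not
reproducible from its description, so the package uses an absolute
response cutoff (adaptive default: 8 robust SDs of the response). Linking
is greedy nearest-neighbour with a hard displacement gate and gap closing
(defaults: displacement 2 px, gaps up to 3 frames). A greedy matcher
instead of a global graph optimiser is a documented simplification: in the
synthetic scenes used for validation, inter-particle spacing is much larger
than per-frame displacement, where greedy and optimal assignments coincide.

Retention follows the strict rules used for the real movies: more than 160
observed frames for 300-frame MSD movies, more than 95 for 100-frame
movies. The estimator is the overlapping-window time average

$$ \mathrm{MSD}(\tau) = \left\langle |r(t + \tau) - r(t)|^2 \right\rangle_t,
   \qquad \tau = 1 \ldots 40 \text{ frames}, $$

with ensemble curves averaged per particle (each particle's time-averaged
curve contributes once — the natural reading of a per-particle histogram
display; averaging over (particle, t) pairs would weight long tracks more).
For free 2-D diffusion the curve is $4 D \tau$, and `fit_msd_diffusion`
returns $D$ = slope/4 with an intercept that equals $4\sigma_{loc}^2$ for a
static localisation error $\sigma_{loc}$. Parameter recovery on 500
simulated particles (300 frames at 4 fps) is within 15% of the generator's
$D$, and the immobile-plus-noise plateau sits at $4\sigma_{loc}^2 \pm 20\%$
— both checked routinely in the test suite.

## FLIP

A square region (1.12 × 1.12 µm) near one cell pole is bleached every 5 s
while frames are acquired every 1 s for 100 s; the mean intensity of a
reference region at the opposite pole reports how fast the labelled pool
exchanges into the bleached zone. The reference curve is bleach-corrected
by the ratio to an unbleached control cell in the same field (the standard
convention); when no control exists, a mono-exponential acquisition-bleach
model fitted to the pre-bleach frames is used, with its rate clamped at
zero or below — acquisition bleaching can only dim the signal, and an
unconstrained fit over so few points would otherwise amplify noise into a
spurious trend over 100 s. The corrected curve is divided by its value at
the last pre-bleach time point, so the normalised signal equals 1 there
exactly.

The simulated FLIP scene models the fluorophore pool as independent point
emitters (default 5000 per cell) diffusing inside a spherocylinder with
specular reflection. A bleach pulse is modelled as a finite dwell (1 s,
ten diffusion sub-steps with removal inside the square), not an
instantaneous mask: the square covers only ~3% of the cell area, so an
instantaneous pulse could remove at most that fraction of a well-mixed
pool per pulse, far less than what a scanned bleach spot removes from a
fast-diffusing pool in practice. With the dwell model, a fully mobile pool
at $D \geq 1$ µm²/s falls below 0.2 of pre-bleach within the 20 pulses,
while an immobile pool stays within noise of 1 — the qualitative contrast
that identifies free diffusion of small molecules inside otherwise frozen
cells.

## Morphometry and uncertainties

Cell volume is a cylinder plus a ball (the two hemispherical cell ends):

$$ V = \pi \left(\tfrac{W}{2}\right)^2 (L - W)
     + \tfrac{4}{3} \pi \left(\tfrac{W}{2}\right)^3 , $$

evaluated at the mean of bootstrapped means of measured lengths and widths.
Each experiment is resampled independently (999 resamples) and the
per-experiment means pooled, mirroring a three-experiment design; the
variance across the pooled bootstrap means gives $dL^2, dW^2$. Gaussian
error propagation gives

$$ dV^2 = \left(\frac{\pi W^2}{4}\right)^2 dL^2
        + \left(\frac{\pi W (2L - W)}{4}\right)^2 dW^2 , $$

and the shrinkage ratio between a hypertonic condition $S$ and control $E$
is $R = S/E$ with $dR^2 = dS^2/E^2 + (S^2/E^4)\,dE^2$ and a 95% CI of
$R \pm 1.96\sqrt{dR^2}$. The normal approximation is the default (the
bootstrapped means are close to normal); a percentile bootstrap on the
ratio is easy to assemble from the returned `boot_means` if preferred. In
the linear limit (variances → 0) the propagation is exact, and both
formulas agree with $10^5$-draw Monte-Carlo variances to within 5% at
coefficients of variation up to 2%.

The table generator draws per-cell lengths ($\mathcal{N}(10, 1)$ µm) and
widths ($\mathcal{N}(4, 0.3)$ µm, truncated below the length) for three
experiments of 150 cells per condition, with a small (0.05 µm)
between-experiment offset, and applies shrink factors (defaults 0.87 in
length, 0.79 in width) to the treated condition — magnitudes chosen to
reproduce the scale of hypertonic shrinkage of exponentially growing
fission yeast, about 45% volume loss. End to end, the reported volume-ratio
CI covers the generator's true ratio in ≥ 90% of seeded replicates.

## The synthetic generator: what it does and does not emulate

The generator renders spherocylindrical cells (7–14 × 3–4 µm at 0.1 µm/px)
with non-overlapping rejection-sampled placement, sub-resolution particles
as Gaussian spots (σ = 1.2 px, peak 120 counts over a background of 5),
dye-filled dead cells (fill 5× the live outline intensity), static
autofluorescent distractor puncta (Poisson mean 2 per cell at 10–30% of
particle brightness), a multiplicative intensity drift from frame 2 onward,
and Gaussian read noise (SD 2 counts) plus a Poisson-like variance term
(0.05 × intensity). Motion models: immobile; free 2-D Brownian steps with
per-axis variance $2 D \Delta t$ and specular reflection at the cell
boundary (reflection rather than rejection, so step lengths are unbiased);
confined diffusion folded at a disc around the start point. One global
integer seed determines every sub-stream, and a fixed seed reproduces
stacks bit-identically.

Deliberate simplifications: single focal plane (no 3-D PSF), no
differential-interference-contrast image formation, binary photobleaching
without photophysics, rigid cells (no growth or drift — the guard that
drops cells whose mask moves between frames exists but is exercised only
as a guard). Consequently, passing tests demonstrate the correctness and
calibration of the *statistics* under realistic noise, drift and
distractors; they do not certify performance on real images with focus
drift, uneven illumination or cell crowding beyond the rendered densities.
Absolute PCC values from real populations (e.g. the contrast between
exponential growth and deep starvation) depend on real droplet numbers and
SNR, which the generator only approximates; what the synthetic conditions
do pin down are the static ceiling ($r = 1$ exactly without noise, ≥ 0.95
with it) and the strict ordering of PCC against the generator's diffusion
coefficient.

## Numerical and interface choices

* Coordinates are 0-based `(row, col)` = `(y, x)` with y increasing
  downward; pixel `(i, j)` is centred at `(j + 0.5, i + 0.5)` px, and
  micrometre positions convert by division with the pixel size.
* Registration is integer-pixel translation only (FFT cross-correlation),
  because the correlation statistic lives on pixel grids; an all-constant
  frame is flagged and passed through unshifted. Raw frames are registered
  before the log transform.
* Problem sizes in the routine test run are deliberately desk-scale
  (192–256 px fields, 4–8 cells, 500 particles, 3000–5000 FLIP emitters);
  they were chosen as the smallest sizes at which the statistical
  tolerances above are comfortably resolved.
* Degenerate inputs are contracts, not crashes: blank segmentation input
  returns zero cells; a zero-variance cell is dropped from the PCC with a
  recorded reason; empty detection frames terminate tracks; bootstrap and
  ratio functions reject empty or non-positive inputs.
* The command-line wrapper (`exec/cfpipe`) adds no logic of its own; every
  subcommand is a thin call into the exported functions, and fixed inputs
  produce bit-identical outputs.

## Known limitations

The greedy linker will swap identities when particles approach within the
displacement gate; the Otsu-based dead-cell split assumes a clear bimodal
contrast (vital-dye protocols provide one, but weakly stained dead cells
would be missed); the FLIP emitter model ignores binding kinetics, so it
cannot represent pools with fast exchange between bound and free states;
and the morphometry model assumes straight cells — bent or septated cells
violate the spherocylinder geometry and should be excluded upstream.
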