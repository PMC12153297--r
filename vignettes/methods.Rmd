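---
title: "Models and methods behind punctadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind punctadyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctadyn)
```

punctadyn quantifies the behaviour of diffraction-limited fluorescent
puncta — flagellar basal bodies tagged through a C-ring subunit being the
motivating case — along three axes: mobility from time-lapse movies,
surface patterning from 3D coordinates, and subunit exchange from FRAP
series. This vignette explains the models, the parameters that matter,
the numerical choices made where the design was genuinely open, and what
the synthetic-data generators do and do not emulate.

## Mobility: detection, linking, and the MSD estimator

**Detection.** Regions without cells are excluded by a mask obtained by
thresholding the time average of the movie. Otsu's method is applied on a
log scale: time-averaged fluorescence images are typically trimodal
(background, diffuse cell body, bright puncta), and a linear Otsu can
latch onto the punctum mode and mask out everything else. Spots are then
local maxima of a scale-normalized Laplacian-of-Gaussian response,
retained when the underlying pixel intensity exceeds the frame mean plus
`k_sd` standard deviations (default `k_sd = 1`). The statistics are
computed within the mask by default — computing them over the whole frame
dilutes them with background and is available as an option
(`stats_in_mask = FALSE`) for data without a meaningful mask. The LoG
scale (`log_sigma_px`, default 2 px) should match the spot radius; at
~0.1 µm/px a diffraction-limited punctum is ~2 px.

**Sub-pixel localization** uses the radial-symmetry-center method: around
a symmetric spot, intensity gradients all point through the center, which
is found in closed form as the least-squares intersection of the gradient
lines (weighted by gradient magnitude over distance to the gradient
centroid). It is iteration-free and reaches a few hundredths of a pixel
on noiseless model spots (asserted in the tests). Flat or gradient-free
windows fall back to the intensity centroid with a warning.

**Linking** connects detections in *consecutive* frames only — there is
no gap closing, so a missed detection terminates a track, which is the
conservative choice when tracks are later screened for length. Within a
frame pair, the assignment is the exact minimum-total-distance matching
(Hungarian algorithm) restricted to pairs within `search_radius_px`
(default 3 px); unmatched detections start new tracks. Detections are
sorted within each frame before matching, making the result independent
of input order. The search radius is applied to the *refined* positions;
whether a pipeline should link raw or refined positions is ambiguous, and
refined positions are the more accurate of the two.

**MSD analysis.** Tracks with at least `seg_len = 20` consecutive
localizations are analyzed in rolling 20-frame segments (stride 1 —
"rolling" is taken literally; the stride is configurable). Within each
segment, the mean squared displacement at lag $i$ averages all $n_i =
L - i$ overlapping displacements. Overlap is implied by the $n_i$
weighting of the estimator and makes the per-lag values correlated but
unbiased. The apparent diffusion coefficient is one quarter of the
$n_i$-weighted least-squares slope of $\langle r^2\rangle_i$ against
$\tau_i = i\,\Delta t$:

$$D_\text{app} = \frac{1}{4}\,
\frac{\sum_i n_i \sum_i n_i \tau_i \langle r^2\rangle_i -
      \sum_i n_i \tau_i \sum_i n_i \langle r^2\rangle_i}
     {\sum_i n_i \sum_i n_i \tau_i^2 - \left(\sum_i n_i \tau_i\right)^2}.$$

The estimator is exact on any affine MSD table (slope/4, any intercept)
and is cross-checked in the tests against a generic weighted regression
to $10^{-10}$. Negative estimates are deliberately *not* clipped: they
are legitimate noise outcomes, and clipping would bias the
false-positive control. The fitted intercept equals $4\sigma^2$ under the
model, and each call reports the intercept-implied localization
uncertainty so users can recalibrate the mobility floor for their own
optics.

**Classification.** A track is mobile when $D_\text{app}$ *strictly
exceeds* `d_min_um2_s` (default 0.0003 µm²/s, a floor set by typical
localization uncertainty at these imaging conditions) in *at least*
`mobile_fraction_min` (default 10%, compared with ≥) of its segments.
"Exceeds" is a strict inequality and "at least" is not — both read
literally from the rule's phrasing. Movies with fewer than two scoreable
tracks carry no useful mobility statistic and are QC-flagged rather than
silently dropped; short tracks are counted, never scored.

## Patterning: unrolled-cylinder Clark–Evans statistics

Cells are assumed roughly cylindrical. Puncta are centered at their mean
and rotated by the singular vectors of the 3×3 scatter matrix
$P^\top P$ of the centered coordinates (equivalently, PCA axes), with
the dominant axis mapped to X. Two conventions make the output
deterministic: the rotation is forced to a proper rotation
($\det = +1$), and the axis is oriented so that cell end 1 has negative
X. End positions are 2D image coordinates; their position along a
possibly tilted axis is recovered by projecting onto the in-plane
component of the axis direction with norm correction
($t = (p_{xy}-c_{xy})\cdot u_{xy}/\lVert u_{xy}\rVert^2$), so moderate
out-of-plane tilt does not foreshorten the length. A consequence worth
stating: quantities derived purely from puncta (NNMD, fitted radius) are
exactly invariant under any rigid motion, while the length — and through
the surface area, the Clark–Evans ratio — is exactly invariant only
under in-plane motions, the transformations image-derived coordinates
can actually differ by.

The cylinder radius comes from an algebraic (Kåsa) least-squares circle
fit to the Y/Z projections: closed-form, deterministic, and adequate at
~25 points per cell; cells with degenerate projections fall back to the
mean radial distance with a flag. Unrolling maps each punctum to
$(x, s = r\theta)$ on a `length × circumference` rectangle. Distances on
that rectangle use a periodic wrap in the circumferential dimension —
the cylinder has no edge there — and hard edges along the axis, where
the cell genuinely ends. A flat-torus mode (`wrap = "both"`, used for
lattice reference patterns) and a no-wrap mode (sensitivity analysis)
are provided.

The Clark–Evans ratio divides the observed mean nearest-neighbour
distance by the Poisson expectation $1/(2\sqrt{\rho})$ at density
$\rho = n/(2\pi r L)$ (lateral surface only, ends excluded; cell volume
is reported as $\pi r^2 L$). Closed-form anchors: coincident points give
0, random patterns center on 1, and a triangular lattice gives the
maximum $2\sqrt{2/\sqrt{3}} \approx 2.1491$. The hard axial edges bias
random-pattern values slightly above 1 (a few percent at 25 puncta on a
4 × 0.8π µm surface); the per-cell null carries the same bias, so
observed-vs-null comparisons are unaffected. For observed cells the
density uses the fitted-circle radius by default; `radius_for_density =
"radial_mean"` matches the convention inside the null generator instead,
and both are reported because the choice is ambiguous at the level of
the procedure's description.

**Randomization null.** Each measured cell is compared with `n_sims =
1000` simulated cells with the same punctum count and length. Each
replicate draws its radius from a Gaussian with the cell's mean radial
distance and radial sd (truncated positive) — propagating cylinder-fit
uncertainty into surface area — places puncta with uniform X and uniform
angle, and is redrawn until all unrolled nearest-neighbour distances
exceed `cutoff_um` (default 0.1 µm, the lateral resolution floor of
structured-illumination imaging; the cutoff alone shifts the null mean
slightly above 1, which the tests assert). The rejection is whole-cell,
not per-point — resampling single points would distort the conditional
distribution — and the loop is bounded by `max_attempts`, erroring out
with the cutoff named rather than hanging on infeasible densities. The
observed value is located in the null by its empirical CDF; the lower
tail, upper tail and a two-sided probability $\min(1, 2\min(F, 1-F))$
are all reported since the sidedness convention is not fixed by the
procedure — summaries use the two-sided value, and the tests verify it
is uniformly calibrated when the observed cell is itself a null draw.
Strain-level inference is a paired two-sided t-test of observed ratios
against per-cell null means; identical vectors are reported as
non-significant with a degeneracy flag instead of a division by zero.

Additional per-cell descriptors follow the same conventions: the
asymmetry ratio (higher over lower punctum count relative to the
midpoint, with $x = 0$ ties counted toward the smaller side and empty
sides flagged as infinite rather than failing) and a 21-bin histogram of
relative axial positions with each cell's orientation randomized by a
seeded coin flip so no side preference is imposed.

## FRAP normalization

Intensities carry three punctum categories — bleached (targeted),
unbleached in the same cell, unbleached in a separate cell — plus field
background ROIs. Per time point the background ROI mean is subtracted
(negatives clamped to zero and counted), each category is averaged and
expressed relative to its own pre-bleach average ("original" = the
single pre-bleach time point). Averaging before normalizing is the
default reading of the procedure; per-ROI normalization first is
available as an option. Replicate means are pooled with an sd across
replicates. No photofading correction is applied — the separate-cell
category is the empirical control for it. The recovery score (last minus
first post-bleach percent of the targeted category) condenses the
static-vs-exchange contrast into one number.

## What the generators emulate — and what they do not

`simulate_tracks` produces 2D Brownian walks (per-axis increment
variance $2D\Delta t$) plus i.i.d. Gaussian localization noise, matching
the estimator's model exactly; 3D membrane diffusion is not modeled
because the tracking geometry (a single TIRF plane) and the estimator
(4Dτ) are both 2D. `render_movie` draws Gaussian spots on a constant
background with Poisson shot noise, Gaussian read noise, and optional
diffuse cell-body fluorescence (without which no realistic cell mask
exists); it does not model astigmatism, reconstruction artifacts,
blinking or acquisition photobleaching. `simulate_cell_puncta` places
puncta on a cylinder under three regimes: uniform random; a triangular
lattice on the unrolled surface (the maximal-dispersion reference; the
geometry of a "grid-like" pattern is otherwise unconstrained, and the
lattice is made commensurate with the circumference so the wrap metric
is exact) with Gaussian jitter; and Gaussian clusters around random
centers. Defaults — length ~4 µm, radius 0.4 µm, ~25 puncta — are
typical mid-log *B. subtilis* dimensions; no measured length/radius
distributions are bundled, so these are configurable conventions, not
data. `simulate_frap` implements the minimal conserving exchange model:
one well-mixed pool per cell, first-order relaxation of each punctum's
labeled fraction toward the pool mean at rate $k$, conserving total
labeled fluorescence (verified against the closed-form exponential).
Passing tests on these generators therefore demonstrates correctness of
the *estimators* under their stated models, not robustness to every
artifact of real microscopy (drift, uneven illumination, overlapping
cells, non-Brownian motion).

## Numerical choices and problem sizes

All generators are bitwise-reproducible given a seed (seeding is scoped
so the caller's RNG stream is untouched). Determinism elsewhere comes
from explicit conventions: sorted detections before assignment,
tie-breaking by the exact matching, the SVD sign rules above. The
rolling-segment classifier uses a cumulative-sum fast path whose
equality with the per-segment definition is asserted to $10^{-12}$.

The test and calibration runs use desk-scale problem sizes chosen to
give comfortable statistical margins in a few minutes of CPU: 500 cells
of 25 puncta for the random-pattern Clark–Evans calibration (tolerance
±0.05 around 1), a 30-site periodic lattice for the 2.149 anchor
(±0.01), 1,000 pure-noise tracks of 240 frames for the false-positive
floor (<5% mobile), 500 repeats of a 400-replicate null for ECDF
uniformity, and an end-to-end rendered experiment of 200 tracks (5%
truly mobile at $D = 0.003$ µm²/s, $\sigma = 0.02$ µm, 240 frames at
$\Delta t = 0.25$ s) recovered within binomial error.

## Known limitations

No drift correction (movies with drift should be excluded upstream), no
gap closing, no confined/anomalous-diffusion models, no
state-segmentation HMMs. The spatial module does not segment cells or
pick end points, and offers no Donnelly-style edge-corrected Clark–Evans
variant — the per-cell randomization null plays that role. FRAP analysis
stops at normalized curves and a net recovery score; rate-constant curve
fitting is out of scope.
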