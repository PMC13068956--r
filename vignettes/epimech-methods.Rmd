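---
title: "Quantification methods for epithelial monolayer mechanics and imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods for epithelial monolayer mechanics and imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimech)
```

epimech implements the bespoke quantification procedures used to
characterise mechanical homeostasis in retinal pigment epithelium (RPE)
monolayers after apoptosis-driven cell-density reduction: nanoindentation
curve analysis, Brillouin spectroscopy analysis, monolayer image
morphometrics, 3D classification of photoreceptor outer segment (POS)
fragments, and the paired replicate statistics that tie them together.
Because the underlying microscopy and instrument data are not publicly
deposited, every pipeline is paired with a seeded synthetic-data generator
that emits the same file shapes *with ground truth attached*; all claims the
test suite makes are claims about recovery of that ground truth.

## Nanoindentation

A spherical probe of radius $R$ (default 10 µm) on a cantilever of
stiffness $k$ (default 0.025 N/m) is driven into the monolayer under
displacement control. Past the contact point $z_c$ the force follows the
Hertz model

$$F = \tfrac{4}{3}\, E_{\mathrm{eff}} \sqrt{R}\, \delta^{3/2},
\qquad \delta = (z - z_c) - F/k,$$

where $E_{\mathrm{eff}} = E/(1-\nu^2)$ is the effective Young's modulus
(no Poisson ratio is assumed or reported) and the $F/k$ term removes the
cantilever's own deflection — at 0.025 N/m and nanonewton forces this
correction is a substantial fraction of a micrometre and cannot be
neglected. The generator solves this implicit relation by damped
fixed-point iteration (the map is contractive for physical parameters), so
generated curves satisfy the model identically.

**Contact point.** The instrument convention restricts the contact-point
fit to samples carrying at most 30% of the maximum load. Within that
window `detect_contact_point()` fits $(z_c, E_{\mathrm{eff}})$ jointly;
for fixed $z_c$ the modulus has a closed-form least-squares solution, so
the search is one-dimensional (coarse grid plus golden-section
refinement), and `detect_contact_point_grid()` provides the exhaustive-grid
oracle the optimiser is tested against. The force entering this objective
is lightly smoothed (moving average, 7 samples by default): the residual
cost around the true contact kink is asymmetric — overshooting $z_c$ is
penalised much harder than undershooting — so unsmoothed noise drags the
estimate systematically early, which propagates into a low-biased modulus.
Smoothing suppresses that bias below half a percent at 2% force noise
without affecting noise-free recovery. The subsequent `fit_hertz()` uses
the raw forces on the segment from the contact point to 2.5 µm of
compliance-corrected depth, computes $R^2$ against the mean-force null on
that segment only, and flags fits with $R^2 > 0.95$ as accepted; only
accepted fits enter `aggregate_matrix_scan()` (mean within each matrix
scan, then mean over scans).

**Oscillatory moduli.** For small oscillations of amplitude
$\delta_{amp}$ about an operating depth $\delta_{op}$, Hertzian contact
linearises to stiffness $S = 2 E^* \sqrt{R\,\delta_{op}}$, so
`compute_dma_moduli()` reports
$E^* = (F_{amp}/\delta_{amp})\,e^{i\varphi} / (2\sqrt{R\,\delta_{op}})$
with storage modulus $E' = \mathrm{Re}\,E^*$ and loss modulus
$E'' = \mathrm{Im}\,E^*$ at each probed frequency (1, 2, 4, 10 Hz). The
instrument software's exact recipe is proprietary; this standard
linearised-contact result is the package's documented choice, and the
generator/analysis pair forms an exact forward–inverse round trip.

A small geometric identity, `probing_depth_fraction()`, expresses the
2.5 µm fitting depth as a percentage of the live cell height
(2.5 of 27.8 µm ≈ 9%): the indentation statistics characterise the
apical-most tenth of the monolayer.

## Brillouin spectroscopy

Each voxel of a Brillouin measurement yields a Stokes/anti-Stokes doublet.
Each peak is fitted with the damped-oscillator Lorentzian

$$I(\omega) = \frac{I_0}{\pi}\,
  \frac{\Gamma\,\omega_B^2}{(\omega^2-\omega_B^2)^2 + \Gamma^2\omega_B^2},$$

whose value at $\omega = \omega_B$ is $I_0/(\pi\Gamma)$. Because the
expression depends only on $\omega^2$, the generator evaluates it on the
full signed axis to produce the mirror doublet. `fit_lorentzian()` runs
Levenberg–Marquardt per sign window (initial shift = window argmax), and
`average_sides()` averages $|\omega_B|$ and $\Gamma$ arithmetically into
the voxel value, falling back to a flagged single-sided value if one fit
fails.

**z-profiles.** Axial scans (2 µm step over 80 µm) traverse hydrogel →
monolayer → medium. `analyze_z_profile()` implements the peak/plateau
dichotomy: Savitzky–Golay smoothing (window 5, order 2 — reasonable for
41-sample profiles; the original analysis states the filter but not its
parameters, so both are configuration); interior-maximum detection with a
minimum width (3 samples) and a minimum prominence (0.02 GHz) to suppress
false peaks; Gaussian refinement of the winning peak bounded by the
derivative's local maximum before and local minimum after the candidate
(the concrete reading adopted for "an appropriate range"); and, when no
admissible peak exists, a plateau branch that finds the onset of the drop
as the first point where a 3-sample moving average of the derivative falls
below −0.005 GHz/µm and reports the mean filtered shift before onset.
Profiles with neither feature are flagged indeterminate and excluded,
mirroring the outlier screening applied to real scans. At 0.005 GHz noise
the dichotomy classifies ≥ 95% of generated profiles correctly over 100
seeds; the prominence threshold (≈ 6 standard deviations of the
post-filter noise at that level) is what carries this margin.

**Raster maps.** 50 × 50 µm maps at 1.5 µm step are linearly rescaled to
8-bit (`scale_map_to_8bit()`, min → 0, max → 255, half-up rounding, with
the inverse mapping retained so byte values stay proportional to shifts)
for external instance segmentation; the pipeline consumes the resulting
mask — or the generator's ground-truth mask — and `region_stats()` reports
mean/SD/count over core, interstitium and whole map. The counts and means
satisfy the exact conservation identity
$n_c \bar x_c + n_i \bar x_i = n \bar x$ for every mask, which the tests
exploit. Segmentation itself is deliberately out of scope: the original
analysis delegates it to an external tool.

## Monolayer image morphometrics

All "a threshold was applied" steps default to Otsu's method (the original
Methods never name one); every threshold is exposed as an argument.
Nuclei counting follows smooth (Gaussian) → threshold → watershed on the
distance map → size filter → count, with density = count / field area.
Cell height is the full vertical extent of the binary cross-section at ten
uniformly spaced foreground columns; fixed, mounted samples flatten the
epithelium, so these heights are lower than live-cell values and no
correction is applied.

**Shape factor.** Cell outlines come from external instance segmentation
(label images); per interior cell the package reports
$q = P/\sqrt{A}$ — the shape-index convention adopted here, since the
source describes a dimensionless shape factor computed from area and
perimeter without printing the formula. Area is the pixel count; the
perimeter estimator is the chamfered crack boundary: the inter-pixel
(taxicab) boundary length minus $(1-\sqrt2/2)$ per corner configuration,
equivalent to the midpoint polygon of the crack contour. This keeps
axis-aligned polygons near-exact (a 20 px square measures $q = 3.94$ vs 4)
and bounds the overestimate on smooth shapes to a few percent (a 30 px
disc measures $q \approx 3.74$ vs $2\sqrt{\pi} \approx 3.545$); the bias
is largest for edges near 22.5° and does not vanish with resolution, which
is acceptable here because the shape factor is used comparatively between
conditions measured at the same resolution. The isoperimetric lower bound
$q \ge 2\sqrt{\pi}$ is never violated from below beyond floating-point
noise.

Microvilli length is the minor axis of the second-moment ellipse of each
thresholded cross-sectional region (exact for filled ellipses, rotation
invariant). The vinculin-style junctional/cytoplasmic ratio slims each
cell ROI by `shrink_px` and takes the junctional region as the complement
band around the outlines; the MRTFA-style nuclear/cytoplasmic ratio zeroes
nuclear pixels and thresholds the remainder so unlabelled background does
not dilute the cytoplasmic mean; the pMLC2-style junctional mean averages
supra-threshold pixels only. All three return exactly 1.0 on uniform
images, and the junctional ratio is documented as not invariant to
additive offsets.

**Extrusions.** Extruded cells appear as very bright transient spots in
the final hours of apoptosis induction. `count_extrusions()` aligns frames
to the first frame by integer-pixel FFT cross-correlation — with bright
transients clipped at median + 5 MAD before correlating, so registration
locks onto the static background texture rather than onto the spots —
then Gaussian-smooths, maximum-projects over time, thresholds and counts
size-filtered components. The default threshold is median + 10 MAD of the
projection rather than Otsu: the spots are rare bright outliers on a
textured background, and an Otsu split of an essentially unimodal
histogram would fabricate foreground when no event exists.

## POS internalisation

The apical actin channel defines a surface: per lateral column, the
physical z of the uppermost supra-threshold voxel (columns without signal
are missing; more than 50% missing aborts). The cut-off is the arithmetic
mean of the surface — a single scalar, exactly as in the original
procedure, rather than a local height. Particles are 26-connected
components of the thresholded POS channel (≥ 4 voxels by default), with
volume = voxel count × voxel volume. A particle is internalised if its
centroid lies strictly below the cut-off, bound otherwise; the tie goes to
bound, which is conservative against over-counting internalisation, and
whether centroid or full-extent classification was used originally is not
stated — centroid is the package's documented default. Counts are
monotone in the cut-off and the two classes partition the particle set for
every threshold, both tested properties. The apical actin area is the
triangulated mesh area of the surface height map over a fixed slice
subset; it equals the lateral footprint exactly for a flat surface and
grows strictly with corrugation.

## Replicate statistics

Technical replicates (or matrix measurements within a sample) are averaged
into one value per biological replicate (`aggregate_technical()`).
`paired_t()` is the two-sided paired t-test on differences (second minus
first argument); `ratio_paired_t()` is the same test on natural-log values
— the standard definition of the "ratio paired" test of a multiplicative
null; base-10 logs would give identical statistics and p-values.
`one_way_anova()` is the classical equal-variance decomposition. No
multiple-testing correction is applied, matching the per-panel reporting
convention of the study design. Star annotations follow the usual caption
thresholds. Simulating null paired data (n = 4 replicates, 2000
simulations) keeps the empirical type-I error of both paired tests inside
the binomial 95% band around 0.05, a calibration the acceptance suite
re-runs.

## Synthetic data: what it does and does not emulate

Every generator is a pure function of its configuration and a seed, and
attaches its ground truth (`truth`) to the returned object; the IO helpers
write the data in the package's standard formats (CSV with fixed column
names, multi-page float TIFF with JSON sidecars) with the truth as a JSON
sidecar. The noise model is additive Gaussian throughout — standard
deviation as a fraction of the signal amplitude for instrument-like
signals, absolute GHz (`noise_sd`) for Brillouin shifts, whose natural
scale is absolute; no noise magnitudes are stated for any instrument in
the source, so the defaults are calibration points for the recovery tests,
not claims about the hardware. Monolayer geometry is a Voronoi
tessellation over jittered grid seeds: it reproduces the polygonal,
confluent organisation that the quantifications actually depend on, but it
is not a biophysical model — no junctional mechanics, no intensity
heterogeneity within compartments, no optical blur or pigment absorption.
The POS generator aligns the monolayer height with the voxel-centre grid
(default z-voxel 0.2 µm), so flat-surface recovery is exact; heights off
the grid recover to within half a voxel. Consequently, passing tests
demonstrate that the pipelines are correct inverse procedures under
idealised image formation; they do not validate segmentation robustness
against real microscopy artefacts.

Coordinates are 0-based with half-open extents in the file formats, z
increases apically, and all physical sizes travel as µm metadata.

## Problem sizes used by the tests and drivers

The test suite and the `analysis/` drivers run on deliberately small
instances chosen to exercise every code path with comfortable statistical
margins: 601-sample indentation curves, 3 × 16-curve matrix scans,
1601-point spectra, 41-sample z-profiles, 34 × 34 raster maps, 0.1 mm²
monolayer fields (~300 cells), 160 × 160 × 86 stacks with ≤ 50 particles,
and 60-frame movies. The recovery margins at these sizes are wide
(sub-percent for the deterministic fits), so conclusions do not hinge on
the instance size.

## Known limitations

Single loading-segment analysis only (no unloading/Oliver–Pharr, no
adhesion models, no substrate correction); no conversion of Brillouin
shift to longitudinal modulus (requires refractive index and density);
instance segmentation of cells is consumed, never produced; the perimeter
estimator's smooth-shape bias noted above; and the extrusion registration
is integer-pixel only.
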