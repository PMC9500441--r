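---
title: "Methods: 3D crypt morphometry, chirality and the synthetic phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D crypt morphometry, chirality and the synthetic phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptmorph)
```

## The measurement model

`cryptmorph` treats a colonic crypt as a filled tubular body descending
from the mucosal surface (`z = 0`, physical units µm throughout). Three
descriptors summarize its architecture, all computed after clipping the
crypt to at most 250 µm below the detected surface so that specimens of
different thickness are comparable:

- **Volume** is voxel count × voxel volume over the filled body
  (basement-membrane wall ∪ enclosed lumen). Whether "crypt volume"
  should include the lumen is a genuine modeling choice; we adopt the
  filled-body convention because the wall-only volume would depend
  sensitively on the apparent membrane thickness, an imaging artifact.
- **Ellipticity (prolate)** comes from the moment-equivalent ellipsoid:
  the eigenvalues λ₁ ≤ λ₂ ≤ λ₃ of the second central moment of the
  filled voxel set give semi-axes `sqrt(5·λ)` (the uniform-solid-ellipsoid
  relation, consistent with the filled-body convention), and
  `e_p = (c − b)/(c − a)`, defined 0 for a sphere. An ideal straight tube
  has `a = b < c` and `e_p = 1`; dilation and distortion lower it. The
  exact preset formula used by commercial rendering software is not
  public, so the definition is exposed as a function argument
  (`ellipticity_fun`) and can be swapped without touching the pipeline.
- **Tortuosity** uses one centerline point per 50-µm optical slice (the
  area centroid of the cross-section; six points a…f at full depth) and
  is the ratio of the summed consecutive chord lengths to the end-to-end
  distance. It is exactly 1 for a straight crypt, scale-invariant, and
  generalizes to shallower crypts by using all available points (≥ 3),
  with the depth actually used recorded per crypt.

## Twist and spiral staircase-like crypts

The chirality of a crypt is the sign of its net rotation about its own
axis, viewed from the mucosal surface into the tissue (counterclockwise
positive). Estimating this from six sampled points is more delicate than
it looks: a least-squares (PCA) axis is biased toward the helix plane at
this sampling density (the sampled y-coordinates of a helix correlate
with depth), which inflates the azimuth sum of a single full turn to
roughly 422°, and the surface-to-bottom chord fails for half-integer
turns, whose endpoints sit 180° apart. We therefore read the twist from
the *second differences* of the xy-projected centerline: a tilted axis
contributes the same lateral step to every displacement, so differencing
twice cancels it exactly, and the azimuth increments of the resulting
vectors equal the per-step rotation for a uniformly sampled helix at any
tilt and any number of turns. The increments (each wrapped to
(−180°, 180°]) are summed and rescaled by (N−1)/(number of increments),
so a full turn reads 360°, a double turn 720°, and multi-turn crypts
accumulate beyond 360° as they should. Second differences below 1 µm are
discarded, which makes straight crypts (whose residual wobble is
sub-voxel centroid jitter) read 0. The wrap step limits the method to
less than half a turn per 50-µm slice — about 2.5 turns over the full
normalization depth, far beyond anything anatomically plausible.

A crypt is called CCW or CW when |Δθ| exceeds 90° (a quarter turn; the
threshold is a package choice — no numeric criterion for "twisted" is
standard — and it is deliberately far above the jitter floor of straight
crypts). Spiral staircase-like crypts are groups of two or more
*adjacent* co-chiral crypts; adjacency is a surface-anchor distance of at
most 150 µm (about two crypt diameters, also exposed as a parameter),
and groups are connected components within each chirality class. The
cohort SSC rate is the percentage of specimens containing at least one
group, rounded half-up to two decimals.

## Segmentation

Crypt cross-sections are detected slice-wise from the PAFhy channel:
every sampled plane (13 µm by default; 66 µm is the coarse setting) is
thresholded (Otsu per slice, or a fixed value for reproducibility runs),
morphologically closed so a thin membrane ring encloses its hole, filled,
and reduced to 2D components gated by area (300–60 000 µm²) and
circularity (≥ 0.3). Sections are linked across slices greedily by
overlap, gated by centroid displacement ≤ max(2 × median section radius,
30 µm); a chain may miss up to two sampled slices, which keeps two crypts
distinct when their sections briefly merge into one component. Chains
covering ≥ 60% of the sampled slices become crypts (this excludes
goblet-blob artifacts); planes between sampled slices are filled by
translating the nearer section to the interpolated centroid, and chains
are extended past their terminal slices — advected along the extrapolated
centroid drift — while the mean intensity under the section stays within
half of its terminal value. That extension is what makes 13-µm and 66-µm
maps of the same specimen agree on volume to within 10%.

Within each filled section, bright components touching the section
boundary are the basement-membrane wall; the enclosed remainder is the
lumen. Wall and lumen labels are disjoint, and morphometry uses their
union.

## Neutrophil mapping

Neutrophils are detected as 26-connected bright components whose physical
volume matches a sphere of 6–14 µm diameter and which are disjoint from
crypt walls; goblet mucus is rendered (and in real tissue, typically is)
larger than that gate, and the membrane itself is far larger, so the size
window does most of the work. Crypt-abscess continuity is a flood fill
from the crypt's lumen through neutrophil-positive voxels with walls
blocking, so stromal cells are retained only when the epithelium is
breached or an explicit bright bridge connects them — the operational
reading of "only neutrophils continuous with the micro-abscess site".
The depth summary is the fraction of cell centroids in the deepest third
of the crypt's clipped extent.

## Cohort statistics

Two-group comparisons follow the conventional normality-guided ladder at
α = 0.05: Shapiro–Wilk on each sample; if both pass, an F test chooses
between Student's and Welch's t; otherwise the Mann–Whitney U test, with
midranks, a tie-corrected variance in the normal approximation, and full
enumeration of all C(n+m, n) assignments when both samples have ≤ 8
values (valid under ties). Spearman correlations use midranks with exact
permutation p-values at n ≤ 7 and the t approximation above. All tests
are two-sided and no multiplicity correction is applied — the package
reports per-comparison p-values, as is conventional for these panels.
Per-specimen sampling selects 5 random crypts without replacement
(seeded); specimens with fewer contribute all crypts with a warning, and
specimens with none are excluded with a warning.

## Classification data preparation and evaluation

Plane images are exported from the PAFhy channel (sagittal = fixed-y,
horizontal = fixed-z). Sagittal images are center-cropped to the largest
square before the bilinear resize to 256 × 256; horizontal images are
resized directly; intensities are divided by the full scale (255 for
8-bit). Augmentation applies, independently and under one seed, each
flip at p = 0.5, a uniform rotation in [−20°, 20°] with reflective
padding, and erasing of one rectangle (2–20% of the area, aspect ratio
0.5–2, filled with the image mean). Stratified-group k-fold assigns whole
specimens to folds, greedily balancing per-fold class counts so no
specimen's images are split and per-fold class counts differ by at most
one specimen. The evaluation layer computes per-class one-vs-rest
confusion counts, accuracy, sensitivity, specificity, precision, F1
(harmonic mean of precision and recall; 0 when TP = 0; a class absent
from the reference reports NA sensitivity rather than 0), and AUC by the
rank statistic with midrank tie credit, macro-averaged without weights.
Display rounding is half-up: two decimals for percentages and AUC, three
for F1. The CNN itself is out of scope — training one is a GPU-scale
exercise whose value lies in its weights — so the score provider is
pluggable, with a nearest-centroid baseline (standardized
specimen-averaged V, e_p, T; inverse-distance softmax) as the reference
implementation that exercises the whole evaluation path.

## The synthetic phantom

Because no public volumes accompany this kind of data, the generator is
first-class, tested code. A crypt is an extruded disk: at every depth z
the cross-section is a circle of the tube radius centred on a centerline
that follows a helix (radius, signed turns) superimposed on a tilted
axis. This construction makes the ground truth analytic: volume is
π·r²·depth exactly; the covariance of the solid is the covariance of the
centerline path plus the in-plane disk term r²/4, integrated densely in
z, which yields exact moment-ellipsoid axes; tortuosity and twist are
evaluated directly on the analytic centerline at 50-µm steps. The PAFhy
channel renders a bright membrane shell (≥ 1.5 voxels thick so it stays
contiguous at coarse grids), a dim wall interior, goblet-mucus ellipsoids
inside the wall sized above the neutrophil gate, and neutrophils as
0.95-intensity spheres placed with a minimum separation so planted counts
are recoverable; the abscess pattern fills the lower lumen contiguously
and breaches the wall, emulating disrupted epithelium. The noise model is
additive Gaussian plus exponential depth attenuation — the simplest model
that stresses slice-wise thresholding the way clearing-imaging
attenuation does. Identical seeds give bit-identical volumes.

Cohort generation draws per-crypt geometry from group-level
distributions fixed once to reflect the reported directions of effect:
UC-like crypts are dilated (radius 45 ± 5 µm vs 32 ± 3 µm in controls),
strongly distorted (helix radius 28 ± 8 µm, |turns| 0.8 ± 0.2, tilt SD
5°), CD-like crypts keep near-normal volume with moderate distortion,
and controls are straight elongated tubes. The printed group means of
the source cohorts are not public, so these numbers are the package's own
realistic choices; what the tests rely on is the *separation structure*
(UC volume and tortuosity above controls by more than one SD; ellipticity
highest in controls), not the absolute values. SSC prevalence is realized
by explicit per-specimen flags — exactly round(prevalence · n) specimens
(13/28 UC-like, 4/18 CD-like, 0/22 control) receive a co-located
co-chiral full-twist pair, while all other crypt anchors sit on a 250-µm
grid, farther apart than the adjacency radius, so flagged counts are
exact by construction. Inflammatory-cell counts per high-power field are
drawn per specimen with a group-dependent coupling to mean crypt volume
(positive in UC-like, weakly negative in CD-like), giving the correlation
module realistic input.

What the phantom does *not* emulate: real basement-membrane texture,
goblet depletion gradients, partial staining, optical anisotropy and
scattering, deformed (non-circular) cross-sections, and branching crypts.
Passing tests on phantoms therefore demonstrate correctness of the
geometry, linking, statistics and bookkeeping — not robustness to every
artifact of real cleared-tissue imaging.

## Numerical choices and problem sizes

Geometric comparisons use a relative tolerance of 1e-6 unless stated;
collinearity for T = 1 is judged at 1e-9 relative. Default voxel pitch is
2 µm isotropic; the examples and tests run at 2–4 µm on grids of roughly
64–160 voxels per side, where a specimen renders and segments in well
under a second to a few seconds. The statistical property checks use 50
replicate cohorts of 10 specimens per group for power and 1000 replicate
null pairs (n = 30 each) for the type-I rate, judged against a 99%
binomial band around 5%. The end-to-end pipeline demo uses 10 specimens
(4/3/3 across groups) with 4 crypts each at 4-µm pitch and runs in about
half a minute; all sizes are parameters, and larger runs only cost time.

## Known limitations

- Segmentation assumes crypts are roughly perpendicular to the surface
  (sections are z-plane components); strongly oblique or branching crypts
  would need oblique reslicing.
- The twist estimator assumes uniform centerline sampling; irregular
  z-spacing would bias the rescaling.
- Otsu per slice presumes bimodal slices; at extreme depth attenuation a
  fixed threshold calibrated on shallow slices is the safer setting.
- The lumen/wall split is geometric (boundary-touching bright components
  are wall); a lumen-filling abscess that touches a breached membrane is
  classified wall at that plane, slightly eroding abscess volume there.
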