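---
title: "Semi-automatic localization of intracranial electrodes from CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automatic localization of intracranial electrodes from CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieegloc)
```

## The problem

Intracranial EEG (iEEG) interpretation — clinical localization of the
epileptogenic zone, or cognitive-neuroscience analyses in a standard space —
depends on knowing where each electrode contact sits relative to brain
anatomy. A platinum contact produces a bright, compact artifact in a
post-implantation CT (thousands of Hounsfield units against soft tissue near
0–100 HU), so a CT co-registered to an anatomical MRI carries enough
information to localize every contact. Doing this by hand, contact by
contact, is slow and operator-dependent.

`ieegloc` implements a semi-automatic pipeline over a co-registered CT and a
binary brain mask:

1. **Masking and thresholding** — the brain mask is dilated or eroded with a
   3×3×3 cubical structuring element (to exclude bright skull or to cover
   surface contacts), and the CT is thresholded, by default at 1,800 HU, with
   an inclusive (`>=`) comparison. The result is a *voxel cloud*: a tibble of
   voxel indices, world-mm coordinates and intensities.
2. **Per-array voxel selection** — interactive 3-D lassoing is replaced by
   programmatic selection: bounding boxes, radius-around-seed-points
   (`select_near_points()`, e.g. the planned implantation geometry), explicit
   26-connected component lists, and a minimum component size that removes
   spurious single-voxel noise and serves as the "manual removal" step for
   cables and markers.
3. **Clustering and localization** — the array's cloud is split into `K`
   clusters (one per contact, `K` from the implantation notes) by K-means on
   the unweighted voxel coordinates in world mm; each contact coordinate is
   the intensity-weighted center of mass of its cluster. The electrode table
   is a tibble, one row per contact.
4. **Numbering** — depth and strip arrays are ordered along their first
   principal component, index 1 at the deep end; grids go through the
   convex-hull procedure described below. Names are `prefix + index`.
5. **Anatomical labeling** — nearest-voxel lookup in a 4-D probabilistic
   atlas (FSL-style layout: 4-D NIfTI plus a TSV of region names), reporting
   ranked probabilities exactly as sampled.
6. **Brain-shift correction** — grids are projected onto a smoothed cortical
   envelope by constrained energy minimization, and the projection vectors
   are propagated to depth electrodes through a Gaussian displacement field.

All coordinates are world-space mm (RAS+ assumed for reporting); voxel
indices are 0-based. Images are never resampled: CT, mask and atlas must
share a pre-registered grid, and the package errors otherwise.
Co-registration, normalization and brain extraction are upstream concerns
for SPM/FSL/FreeSurfer-class tools.

## K-means details

K-means is Lloyd's algorithm (`stats::kmeans`), initialized by k-means++
with at least 10 restarts under a fixed seed, keeping the best
within-cluster sum of squares; a final reassign/recompute polish guarantees
every voxel ends in its nearest centroid's cluster. When the cloud's
26-connected components number exactly `K` — the well-separated regime — the
component centroids are tried as one additional deterministic start. This
matters in practice: on a 64-contact grid, k-means++ restarts alone
occasionally merge two adjacent contacts and split another (the classic
low-threshold failure mode), while the informed start finds the correct
partition whenever the components are clean. Intensities deliberately do
*not* enter the clustering, only the center-of-mass step.

## Grid numbering

Rectangular grids are numbered geometrically:

1. Project the `K` contact coordinates onto their first two principal
   components.
2. Compute the 2-D convex hull and the transition angle at every hull vertex
   (the absolute turn between incoming and outgoing segments, in degrees;
   for a convex polygon these sum to 360°).
3. The four largest angles mark the grid corners (ties break toward vertices
   farthest from the hull centroid — corners are extremal).
4. Build an "ideal" grid by bilinear interpolation of the four corner
   contacts over the known rows × cols lattice, indices row-major. The
   corner nearest the first stored contact becomes corner 1; whether the
   second corner spans the row or the column edge is decided by comparing
   edge lengths against `(cols-1)·pitch` and `(rows-1)·pitch`.
5. Fit a least-squares sphere to the real coordinates (algebraic fit refined
   by geometric residual minimization) and project the ideal grid radially
   onto it. Exactly coplanar grids make the sphere degenerate; when the
   fitted radius exceeds 10× the grid extent the fit falls back to a plane
   and the projection becomes orthogonal.
6. Assign ideal indices to real contacts greedily from short to long
   real–ideal distance (distance ties break by storage id, making the result
   deterministic).
7. Refine by hill-climbing over swaps of lattice-adjacent index pairs,
   first minimizing the summed real–ideal distances, then the summed
   distances between lattice-adjacent real contacts; each sweep restarts
   after an accepted swap, and both objectives strictly decrease, so the
   procedure terminates. Both objective trajectories are kept as
   diagnostics; on every instance we tested, the second phase never undid a
   first-phase improvement.
8. The global orientation (8 lattice symmetries) is genuinely unidentifiable
   from geometry; `flip_rotate()` applies the documented flips/rotations
   from the implantation diagram.

On noiseless grids from 2×4 to 8×8, flat or on 70–90 mm spherical caps, the
recovered numbering equals the ground truth up to a lattice symmetry in
every case we generate (and exactly, after normalization).

The "deepest contact" of a depth array is resolved by an explicit `deep_end`
coordinate when available; otherwise the endpoint farther from the
brain-mask boundary (measured by a Euclidean distance transform inside the
mask) is taken as the tip.

## Cortical envelope and brain-shift correction

Peri-operative fluid build-up displaces subdural grids by several mm
relative to the pre-implantation anatomy. The correction projects grids
back to a *smoothed cortical envelope* (SCE): the brain mask is closed with
a Euclidean ball of radius 8 mm (bridging sulci — the EDT-based closing pads
its domain so the dilation is never clipped at the field of view), the
voxel-face boundary surface of the closed mask is extracted, and 20
iterations of Laplacian smoothing with factor 0.5 remove the staircase. At
1 mm resolution this yields roughly 2 nodes per mm², so constraining
contacts to mesh nodes costs well under 1 mm of discretization error. Only
surface nodes matter for the constraint, so a triangular surface mesh is
used.

Projection minimizes the spring-grid energy

$$\sum_k \lVert L_k - L_k^0 \rVert^2 + \sum_{i<j} a_{ij}\,(d_{ij} - d_{ij}^0)^2$$

subject to every $L_k$ coinciding with a mesh node, where $a_{ij} = 1$ for
lattice neighbors, $d_{ij}$ are inter-contact distances and $L^0$ the input
coordinates. The constraint is circular (the nearest node depends on where
the contact is), which we resolve by alternating minimization: snap to
nearest nodes, minimize the unconstrained energy continuously (L-BFGS with
analytic gradients), re-snap, and stop when the assignment is stable —
accepting only assignment changes that strictly decrease the snapped
energy, so the reported energy is non-increasing. A final coordinate
descent over each contact's ~30 nearest candidate nodes removes the
residual sensitivity of nearest-node snapping to sub-millimeter mesh
ripple; on 2×2 test cases the result matches an exhaustive search over
candidate node combinations exactly.

Depth electrodes implanted alongside grids are translated by the
displacement field
$$F_j = \frac{\sum_k w_{jk}\, w'_{jk}\, D_k}{\sum_k w_{jk}}, \qquad
w_{jk} = e^{-\lVert L_j - L_k\rVert^2/\sigma_R^2}, \quad
w'_{jk} = e^{-\lVert L_j - L_k\rVert^2/\sigma_D^2},$$
with $D_k$ the grid projection vectors, distances measured to the projected
grid contacts, and $2\sigma_D$ the mean distance of the grid contacts to the
SCE centroid. $\sigma_R$ defaults to half the grid pitch and is exposed as a
parameter. The attenuation weight is implemented exactly as defined; its
motivation (contacts near the brain's geometric center are less affected)
suggests a variant where $w'$ depends on the depth contact's distance to
the SCE centroid instead, available as `attenuation = "centroid"`. The
field obeys $F = D$ at distance zero from a single grid contact,
$\lVert F \rVert \to 0$ far away, exact cancellation between opposite
displacements, and $\lVert F_j \rVert \le \max_k \lVert D_k \rVert$.

One empirical note from the test suite: for a 2×2 grid pushed 5 mm into a
25 mm sphere, the *global* energy minimum (verified by exhaustive node
search) spreads neighbor distances ~5–10 % beyond the original pitch — the
displacement term prefers the nearest-surface direction, which diverges
radially, and the spring term only partially counters it. This is a
property of the energy, not of the optimizer.

## Validation statistics

- `gold_standard()` — the componentwise mean of repeated (expert or
  simulated-rater) localizations per contact.
- `localization_errors()` — per-contact Euclidean distances.
- `krippendorff_alpha()` — interval-data alpha, $1 - D_o/D_e$ with the
  squared-difference metric, within-unit ordered pairs weighted by
  $1/(m_u-1)$, expected disagreement over all pooled value pairs. 3-D
  coordinates enter with each contact *component* (x, y, z) as a separate
  unit, since alpha is a scalar-rating coefficient; per-axis reporting is a
  matter of slicing the ratings matrix. All-identical data defines
  $\alpha = 1$.
- `paired_permutation_test()` — paired t statistic with a sign-flipping null
  (100,000 flips by default), two-sided, the observed permutation included
  so $p \ge 1/(n_{perm}+1)$. Re-partitioning the pooled samples is the
  other common scheme; for paired designs the sign-flip null is the
  exchangeable one, and it is what "permutation paired t-test" names.
  Constant nonzero differences give an infinite t whose only ties under
  flipping are the two all-equal sign patterns.

## The synthetic phantom

Patient images cannot ship with a package, so every stage is exercised on
synthetic CT phantoms with known ground truth (`make_phantom()`,
`standard_phantom()`):

- **Geometry** — a spherical brain mask (radius 80 mm in the standard
  phantom) at ~50 HU background, a 3 mm skull shell at 1,500 HU placed 10 mm
  outside the brain (so that up to ±5 mask iterations never reach it), grids
  on a spherical cap at exact 10 mm pitch via the exponential map (the
  geodesic distance from the cap center to contact (r, c) is exactly
  `pitch · sqrt(dr² + dc²)`; exactly uniform pitch in both lattice
  directions is impossible on a sphere), and collinear depth arrays at
  exact 5, 6 or 10 mm pitch, entering 50° off the cap axis so the two
  arrays stay ≥ 15° apart.
- **Artifact kernel** — each contact adds a truncated Gaussian (cutoff
  2 sd) with peak 3,200 HU and sd 1.5 mm for grid contacts, 1.3 mm for
  depth contacts. These widths are chosen to reproduce CT metal blooming
  phenomenology on a 1 mm grid: every contact keeps voxels above 2,200 HU
  at any sub-voxel placement with a 3-sigma noise margin
  (3200·exp(−0.375/1.69) ≈ 2560 HU at the worst 0.87 mm offset), 5 mm-pitch
  depth contacts merge below ~1,000 HU (midpoint sum ≈ 1,007 HU) and
  separate at 1,200 HU. A narrower kernel (e.g. sd 0.75 mm) would make
  contacts vanish from high-threshold sweeps entirely, which real contact
  artifacts do not do.
- **Noise** — additive Gaussian, sd 100 HU in the study conditions;
  18 sigma below threshold for background, so spurious voxels require the
  skull (excluded by the mask) or extreme tails (removed by the minimum
  component size of 2).
- **Raters** — `simulate_raters()` adds isotropic Gaussian jitter per rater
  and contact, giving chi-distributed error norms with known closed forms
  for calibration tests.

What the phantom does *not* emulate: beam hardening, streak artifacts,
partial skull contact of real grids, anisotropic voxels, registration
error between CT and mask, and anatomy-shaped (non-spherical) brains.
Passing the simulation studies therefore demonstrates the correctness and
internal robustness of the algorithms under controlled conditions, not
performance on clinical images.

## Simulated validation studies

Three study functions mirror the validation design that a multi-rater
evaluation would use, at desk scale:

- `run_localization_study()` — 50 standard phantoms (8×8 or 4×5 grid plus
  an 8–10-contact depth array each, noise sd 100 HU), full pipeline at
  1,800 HU, per-contact error against truth via bijective greedy nearest
  matching. Typical result: ~0.11 mm mean over ~2,500 contacts.
- `run_robustness_study()` — one fixed phantom localized under 5
  configurations (thresholds 1,200/1,450/1,700/1,950/2,200 HU paired with
  mask-iteration deltas −1/0/+1/0/−1 around each array's baseline: grids
  dilate by 4 so surface artifacts sit inside the mask, depth arrays use
  the delta alone). Reports each run's distance to the across-run mean
  coordinate (typically ~0.1 mm) and Krippendorff's alpha across
  configurations-as-raters (typically > 0.9999).
- `scripts/acceptance.R` recomputes these quantities from scratch.

Problem sizes were chosen so the whole suite runs in minutes on one CPU:
phantom volumes are 124×124×128 at 1 mm, envelope tests use 25 mm spheres
in 64³ volumes except the brain-shift recovery study, which runs on the
full 80 mm study sphere; exhaustive oracles run at sizes where enumeration
is exact (≤ 12-voxel clusterings, 2×3 assignment problems, 2⁵ sign
patterns, candidate-node products).

## Known limitations

- Component selection, not lassoing: arrays whose artifacts touch (a cable
  crossing a grid at identical intensity) need a tight selection radius or
  explicit component lists.
- The number of contacts `K` is an input, never estimated.
- The global grid orientation requires the implantation diagram
  (`flip_rotate()`); no automatic resolution is attempted.
- Atlas labeling is volumetric nearest-voxel lookup; surface-parcellation
  lookup is out of scope.
- The envelope mesher assumes the mask's world frame has x = 0 as the
  midline when splitting hemispheres.
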