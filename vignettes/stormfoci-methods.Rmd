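---
title: "Methods: coordinate-based SMLM analysis in stormfoci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coordinate-based SMLM analysis in stormfoci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stormfoci)
```

This vignette is the package's own account of the methods it implements:
the models and their assumptions, the parameters that matter, the
numerical choices, and what the synthetic-data tests do and do not
establish.

## The data model

The unit of data is a *localization*: one detected emitter with
coordinates (nm), a photon count, a frame index and a channel tag
(`loc_table`). All downstream structure measurements are performed on 2D
(x, y) projections; the z coordinate is used only by the 3D Voronoi
denoising step. This split mirrors common practice for astigmatic 3D
STORM, where axial precision is markedly worse than lateral precision and
size estimates in z would be dominated by it.

### Localization precision

Per-axis precision comes from the Thompson–Larson–Webb formula

$$\sigma_{x}^2 = \frac{s^2}{N} + \frac{a^2}{12N} + \frac{8\pi s^4 b^2}{a^2 N^2},$$

with PSF width $s$, photons $N$, pixel size $a$ and background $b$
(photons/pixel), and the combined lateral precision is
$\sigma=\sqrt{\sigma_x^2+\sigma_y^2}$. The quality filter keeps
localizations with at least `min_photons = 1000` photons *and*
$\sigma \le$ `max_sigma = 15` nm. We read "precision lower than 15 nm"
as *worse than* (numerically larger than) 15 nm: the literal reading
would discard the best localizations, which cannot be the intent of a
quality filter. The filter is idempotent by construction.

### Blinking and frame linking

A fluorophore that stays on across consecutive camera frames produces one
localization per frame. `link_frames()` merges chains of same-channel
localizations that stay within `link_radius` of the chain's running
photon-weighted centroid and within `max_gap_frames = 10` frames of its
last member, keeping the photon-weighted mean position, the summed photon
count and the first frame. Two free choices here were genuinely open:

* `link_radius` is not a published constant; the default 50 nm is roughly
  three times the worst accepted combined precision — large enough to
  capture jitter of a single emitter, small enough not to bridge
  neighboring structures.
* gating is *centroid-anchored* (distance to the running photon-weighted
  mean) rather than first-localization-anchored; the centroid is the
  lower-variance anchor.

A consequence worth knowing: in very dense structures two *different*
molecules closer than `link_radius` that blink in overlapping frame
windows can merge into one record. This depresses molecule-count
estimates by a few percent on dense filaments (visible in the
parameter-recovery tests) and is a faithful property of frame-linking on
real data, not an artifact of the simulator.

### Channel registration

Registration is translation-only (the mean of per-pair fiducial
displacements, i.e. the least-squares rigid shift); chromatic aberration
field corrections are assumed applied upstream by the acquisition
software.

## Denoising

Two complementary filters remove non-specific background:

1. **Voronoi cell volume.** Each localization's 3D Voronoi cell volume is
   inversely proportional to local density. Cells larger than the *median*
   bounded-cell volume of the dataset are discarded (`threshold = "auto"`);
   a manual threshold outside the band between the mean and the median of
   the volume distribution triggers a warning, since that band is the
   recommended operating range. Unbounded (hull-adjacent) cells are always
   rejected — they sit at the edge of the acquisition volume where density
   is undefined. Published accounts quote absolute thresholds of order
   1e-5 nm^3, dimensionally implausible for cell volumes (likely inverse
   densities); we therefore treat the threshold as data-driven and never
   hard-code those constants.
2. **Neighbor counts.** A localization is kept iff it has at least
   `min_same = 30` same-channel *or* `min_cross = 10` cross-channel
   neighbors within `radius = 100` nm (closed ball, self excluded). The
   thresholds correspond to the number of detections produced by one
   isolated labeled antibody, so the filter rejects isolated non-specific
   labels while keeping structure-bound ones. `radius = "auto"` recomputes
   the mean + 3 SD of first-nearest-neighbor distances, the rule behind
   the published 100–150 nm range.

The median Voronoi rule by construction removes half of the dataset's
bounded cells; it presupposes background-dominated raw data (true of real
acquisitions, and of our synthetic test scenes, where background
contributes ≥ half of the localizations). On structure-dominated input it
would clip structure; this is the main reason the threshold is
configurable.

No installed R package computes 3D Voronoi tessellations, so the 3D step
delegates to Python's scipy.spatial (bundled helper, plain CSV interface);
the 2D fallback uses deldir. Both return exact polygon volumes/areas —
interior cells of a cubic lattice come out exactly at spacing³, which the
tests assert.

## Cluster segmentation and extension

Clusters are connected components of the 2D Delaunay triangulation after
removing all edges longer than `edge_threshold = 30` nm (`"auto"`: the
median Delaunay edge length). Because the Euclidean minimum spanning tree
is a subgraph of the Delaunay triangulation, these components are
*identical* to the components of the full distance-threshold graph at the
same cutoff — an equivalence the acceptance tests verify against a
brute-force oracle on random instances. Components smaller than
`min_size = 5` localizations are labeled noise; the published analyses
note that clusters of ~5–10 molecules sit at the detection limit, and an
explicit floor makes that rule reproducible.

A cluster's **extension** is the maximum over node pairs of the
shortest-path length (Euclidean edge weights) within the thresholded
Delaunay subgraph — the weighted graph diameter. Unlike a bounding-box or
PCA length, the shortest path follows curvature, making it a filament
length proxy; for globular clusters it is a diameter. The arg-max node
pair defines the *filament ends* used by the end-to-point metric; ties
are broken by the lexicographically smallest index pair so output is
deterministic. Extension is invariant under rigid motion (tested) and on
noisy straight filaments exceeds the backbone length by the labeling
broadening at both ends (see the simulator section).

**Molecule counts** divide a cluster's localization count by a
calibration: the number of localizations an isolated labeled antibody
produces under identical processing. The published description uses the
"expected number" (a mean) in its primary definition and a median in one
application; we default to the **mean** (`calibration_profile(stat =
"mean")`) because localization counts accumulate additively — under a
skewed blinking distribution the total scales with the mean, and dividing
by the median would overestimate molecule numbers by the mean/median
ratio (~1.4 for a geometric distribution). The median remains available
as an option. Counts are rounded half-away-from-zero; the raw quotient is
retained for statistics.

**Helix geometry** (`helix_expectation`) converts filament length to
expected monomer and nucleotide counts: with 9 nm pitch, 6 monomers per
turn and 3 nt per monomer, a length L covers L/9 turns, 2L/3 monomers and
2L nt — for L = 200 nm, 133.3 monomers (~130 to the nearest ten, the
reporting convention) engaging ~400 nt.

## Colocalization

Each query-channel cluster is matched to the partner-channel cluster with
the nearest photon-weighted centroid (ties: lower id). Three distances
are reported per pair:

* **C2C** — distance between photon-weighted centroids;
* **P2P** — *median* over query-cluster localizations of the distance to
  the nearest localization in the matched partner cluster. P2P is
  directional; `both_directions = TRUE` also reports the reverse, since
  the published wording is ambiguous about direction;
* **E2P** — minimum over the two filament ends of the distance to the
  matched partner cluster's nearest localization.

A pair is *colocalized* when C2C < 200 nm (protein–protein) or < 100 nm
(ssDNA–RPA); `coloc_fraction()` aggregates per cell. Distance
distributions can be reported for all nearest pairs or for the
below-threshold subset — published figures vary, so both are available
(filter the `pair_metrics` rows on `colocalized`).

### Bivariate Ripley's K and its envelope

$$K_{12}(r) = \frac{A}{n_A n_B}\sum_i\sum_j \mathbf{1}[d(a_i,b_j)\le r],$$

with A the nucleus ROI area; under independent CSR,
$E\,K_{12}(r)=\pi r^2$ up to boundary terms. **No analytic edge
correction is applied** — deliberately. The envelope compares the
observed curve against the same uncorrected estimator applied to
randomized data (query-channel centroids resampled uniformly inside the
nucleus polygon, partner channel fixed, `n_rand = 100`, pointwise
2.5/97.5 percentiles), so boundary bias cancels in the comparison. The
tests verify both faces of this choice: the raw estimator matches the
*exact* uncorrected CSR expectation in a square,
$\pi r^2 - 8r^3/(3L) + r^4/(2L^2)$, and the envelope covers CSR scenes at
the nominal rate while planted 30 nm pairing escapes above the upper
envelope in the 20–100 nm range. An observed curve above / below / within
the envelope is classified clustering / exclusion / independence;
the summary classification flags any exceedance at any radius.
Randomizing both channels is available as an option.

## Statistics

`maxt_compare()` implements a simultaneous multi-group comparison for
unbalanced, non-normal, heteroscedastic measurements (cluster sizes,
extensions): data are log-transformed (zeros shifted by half the smallest
positive value), all pairwise Welch t statistics are computed with
unpooled variances, and familywise-adjusted p-values come from a seeded
parametric bootstrap of the max-|t| null — group means drawn as normals
with plug-in standard errors, group variances as scaled chi-squares with
the observed degrees of freedom, preserving the correlation between
statistics sharing a group. This is a Tukey–Kramer-style single-step
adjustment; it was re-implemented rather than bound to an external
package, and is validated by its operating characteristics (familywise
error within [0.02, 0.08] under a 5-group heteroscedastic log-normal
null; adjusted ≥ raw p for every pair, enforced exactly by flooring the
bootstrap p at the analytic Welch p so Monte-Carlo noise cannot break
monotonicity). `n_draws = 1e5` gives ~0.003 resolution near p = 0.05.

`wilcoxon_ranksum()` enumerates all rank assignments exactly (midranks
for ties) for combined n ≤ 20 — so symmetric inputs give p = 1 exactly
and {1,2,3} vs {4,5,6} gives p = 0.1 — and uses the tie/continuity
corrected normal approximation otherwise. `spearman_rho()` is
rank-then-Pearson with average ranks, undefined (NA with warning) for
constant input.

## The synthetic scene generator

`render_scene()` is a first-class, tested module: its point is to state
an explicit imaging model under which ground truth is known, so that
denoising, segmentation, extension, colocalization and counting can be
validated end to end.

What it models, with defaults and rationale:

| parameter | default | why |
|---|---|---|
| antibody displacement | 15 nm, uniformly oriented fixed-magnitude 3D vector | the size of the primary+secondary antibody stack; a Gaussian-magnitude mode is available |
| labeling efficiency | 1 | detection losses are folded into the antibody calibration in the published workflow; estimates scale linearly with efficiency when it is lowered |
| blink events / fluorophore | geometric, median 8 | re-blinking of dSTORM fluorophores; matched to the calibration profile so counting tests are self-consistent |
| burst length | 1–3 consecutive frames per event | one localization per frame while on; exercises `link_frames()`, which collapses bursts back to events |
| photons / localization | log-normal, median 2000, sdlog 0.4 | puts ~4% of localizations below the 1000-photon cut |
| PSF σ / pixel / background | 150 nm / 160 nm / 16 photons/pixel | yields a median combined precision of ~10 nm through the Thompson formula |
| residual lateral σ | 11 nm | see below |
| axial noise | 2 × lateral per-axis σ | typical astigmatic 3D penalty |
| background | 100 localizations/µm², uniform in the ROI, z uniform in ±250 nm | non-specific staining floor |

**The residual broadening term.** Component-based accounting (precision
~10 nm, antibody ~15 nm, sampling ~5 nm) predicts a resolution near
30 nm FWHM, while the empirical cross-section of straight filaments is
~40 nm — the surplus being attributed to antibody steric hindrance and
thermal movement and residual aberrations. The simulator carries this
surplus as an explicit isotropic lateral Gaussian of
σ = √((40/2.355)² − (30/2.355)²) ≈ 11 nm, derived from that published
discrepancy *a priori* (not fitted to any test). With it, rendered
straight filaments show a fitted cross-section FWHM inside the 30–50 nm
band the tests assert; without it the simulator cannot exceed ~28 nm and
would be unrealistically sharp.

**Blinking vs frame linking.** Blink events of one fluorophore are
scattered across the acquisition (separated by far more than the 10-frame
linking gap), while the localizations *within* one event are consecutive.
Post-linking, one fluorophore therefore contributes approximately its
event count — which is what the isolated-antibody calibration measures.
Had all of a fluorophore's localizations been consecutive, linking would
collapse every fluorophore to a single record and the published
30-neighbor threshold (one antibody's worth of detections) could not
reject isolated antibodies.

What the generator does **not** model: raw camera frames and PSF physics,
dipole orientation effects, astigmatic z-encoding and its depth-dependent
aberrations, drift and its correction residuals, fluorophore
photophysics beyond the geometric event count, chromatic aberration
fields, and nuclear context (chromatin density variations, nucleoli). A
green parameter-recovery test therefore establishes that the *analysis*
is correct under the declared model, not that the model captures every
property of a given microscope.

## Numerical choices and degenerate inputs

* Closed balls everywhere: ties at exactly the radius or threshold are
  included (with a 1e-12 relative slack against floating-point noise at
  the rim).
* Duplicate 2D points (deldir drops them) are re-attached to their
  representative with zero-length edges, so they always share its
  cluster.
* Collinear point sets get an explicit bounding window for the
  triangulation; fewer than 3 points yield a single trivial cluster with
  a warning; fewer than 5 points, or exactly coplanar 3D input, are
  errors for the 3D tessellation (with a pointer to the 2D fallback).
* `filter_quality` refuses to run without a `sigma` column rather than
  silently passing everything.
* Pipeline cells with an empty partner channel produce NA distances and
  `colocalized = FALSE`, never silent drops; empty cells are skipped with
  a warning in `coloc_fraction`.
* All Monte-Carlo components (`ripley_envelope`, `maxt_compare`,
  `render_scene`, `run_pipeline`) take explicit seeds; equal seeds give
  identical output.

## Known limitations

* Registration is translation-only; rotational/chromatic field errors
  must be corrected upstream.
* Extension underestimates the contour length of strongly coiled
  filaments (2D projection plus graph shortcuts) — the published analyses
  note the same limitation.
* Molecule counts are relative to the antibody calibration; absolute
  stoichiometry is out of reach for antibody-based SMLM.
* The max-t adjustment assumes approximate normality of group means on
  the log scale; for tiny groups (n = 3–5) with extreme skew the
  bootstrap is approximate, which is why the operating-characteristic
  test pins the familywise error band rather than exact p-values.
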