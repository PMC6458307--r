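---
title: "Methods: post-processing and spatial statistics for two-color SMLM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-processing and spatial statistics for two-color SMLM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlmpipe)
```

This vignette is the package's account of what it computes and why the
numerical choices are what they are. The setting is dual-color dSTORM of
membrane receptors: each acquisition yields a table of single-fluorophore
localizations (blinks) across thousands of frames, and the scientific
questions are (i) how strongly each receptor species clusters at the
nanoscale, (ii) whether and how strongly the two species colocalize, and
(iii) how mobile the receptors are.

## The localization table and its imperfections

A localization table is not a molecule list. Three artifacts stand between
the two, and the post-processing chain addresses them in a fixed order:

1. **Same-frame duplicates** — multi-emitter fitting can report one
   molecule several times in one frame. Within each frame and channel,
   localizations closer than the pairwise duplicate radius (the larger of
   the two uncertainties, by default) are grouped transitively and each
   group keeps only its smallest-uncertainty member. This step is a
   *removal*, not an averaging: averaging is reserved for blink merging,
   which has the frame structure needed to do it correctly.
2. **Poor localizations** — rows with uncertainty strictly above 20 nm are
   eliminated. The inequality is strict, so a row at exactly 20 nm
   survives; the boundary convention matters for reproducibility and is
   pinned by a test.
3. **Spurious isolated detections** — a localization needs at least 2
   neighbors within 50 nm (closed ball, self excluded) to be kept. The
   filter is a single pass on the pre-filter set: removals do not cascade,
   because an iterated filter would erode cluster edges in a way that is
   hard to reason about and is not part of the standard chain. Excluding
   self is deliberate: with self-inclusion, "at least two neighbors"
   would degenerate to "at least one".
4. **Stage drift** — estimated from fiducial beads (below) and subtracted
   per frame.
5. **Re-blinking** — localizations of one channel within 20 nm of an
   active chain's running centroid in consecutive frames are linked
   greedily in frame order, and each chain collapses to its
   inverse-variance weighted mean, with combined uncertainty
   `1/σ_c² = Σ 1/σ_i²` and the chain's first frame. The default maximum
   dark gap is 0 (consecutive frames only); it is configurable because
   real fluorophores re-activate after long dark times, and a gap equal
   to the acquisition length turns the merge into a purely spatial
   grouping (useful on sparse fields, where we test molecule-count
   recovery within 5 %).

Steps run in the printed order; a dedicated test constructs a table on
which permuting steps 1 and 3 changes the result, so the order is pinned
behaviorally, not just by documentation.

Fiducial rows are exempt from the filters (they must survive until drift
estimation) and are dropped at the end of the chain.

### Drift estimation

Each bead trace (per channel) is referenced to its *own mean position*
rather than its first observation: anchoring on the raw frame-0 position
would inject that single frame's localization noise into every corrected
frame as a constant offset (~`σ/√n_beads`, i.e. larger than the 1 nm
error budget at 2 beads and σ = 2 nm). Traces are averaged per frame,
smoothed with a centered 10-frame moving average whose window shrinks
*symmetrically* at the edges (an asymmetric edge window biases linear
ramps), missing frames are linearly interpolated, and the path is pinned
to (0, 0) at frame 0 via the intercept of a linear fit over the first 150
frames — unbiased for slowly varying drift and far less noisy than the
raw frame-0 value. Synthetic round trips (inject → estimate → correct)
must recover a 0.5 nm/frame path with RMS error below 1 nm.

### Channel registration

Beads visible in both channels are collapsed to per-bead centroids,
matched moving→fixed by nearest centroid, and mapped with a least-squares
bivariate polynomial (degree 1 by default — the minimum consistent with
bead-based alignment; degree 2 available for field curvature). The
matching step is the fragile part: it is only unambiguous when beads are
separated by more than the warp displacement, which is why the synthetic
generator rejection-samples bead positions to a minimum separation
(500 nm by default) — the same property a well-diluted bead preparation
has in practice. Collinear bead geometries are rejected with a
conditioning error rather than silently extrapolated.

## Region of interest

Cluster statistics are computed on a square window (3 × 3 µm by default)
placed "in the middle of the cell". The placement is determinized as the
centroid of the non-fiducial localizations, iterated to a fixed point:
the box is recentered on the centroid of the rows it currently contains
until the retained set stops changing. The fixed point makes re-selection
idempotent (selecting again returns exactly the same rows), which a
single centroid pass does not guarantee for asymmetric fields. Membership
is half-open (`[x0, x0+s) × [y0, y0+s)`), so tiled windows never double
count. A manual center override exists for deliberately placed ROIs.

## Cluster statistics

**Hopkins index.** Squared-distance variant: per iteration, `m` uniform
test positions and `m` sampled data points give
`Σu²/(Σu² + Σw²)`, averaged over 100 iterations; `m` defaults to
`min(0.1·n, 100)`. Under CSR the expectation is 0.5 — the package's first
calibration quantity (mean over 100 CSR fields of n = 2000 must land in
[0.48, 0.52]). Values near 1 indicate clustering; a regular lattice falls
below 0.5. A `subsample_n` option supports computing the index on fixed-
size subsamples; it is off by default.

**Ripley's K/L/H.** `K(r) = (area/n²) Σ_{i≠j} w_ij 1[d_ij ≤ r]`,
`L = √(K/π)`, `H = L − r`; the H peak height measures the excess density
of molecules within clusters and the peak radius the cluster scale. Two
edge corrections: toroidal (wrapped distances, exact for synthetic fields
generated on the torus — the default for validation work) and Ripley's
isotropic circle-arc weight for real rectangular ROIs (valid for
`r ≤ min(side)/2`, which is enforced). The default grid is 50 radii over
0–500 nm, covering the 100–200 nm nanocluster scale with ~10 nm
resolution.

**DBSCAN.** Standard semantics (core = ≥ `min_pts` points within `eps`
including self; clusters = density-connected components; remaining points
noise), with one determinization: border points join the cluster of their
*nearest* core (ties to the lowest index) rather than the first cluster
to reach them, so labels are order-independent and can be compared
verbatim against an independent transitive-closure oracle — which the
test suite does on 200 random instances. Per-cluster *diameter* is the
maximum pairwise distance ("diameter" read literally), and the relative
cluster density is `size/diameter` (molecules per nm); the per-ROI
summary is the unweighted mean over clusters. Defaults `eps = 50 nm`,
`min_pts = 10` keep CSR backgrounds at typical ROI densities mostly
labeled as noise; both are echoed in every output.

**Getis-type analysis.** Each point gets
`G_i = [count within d / (n−1)] / [πd²/area]` — its local neighbor share
relative to the CSR expectation. Points above the 95th percentile of a
pooled Monte-Carlo CSR null (same n, same region) are flagged as locally
clustered; flagged points within `d` of each other form components, and
components of ≥ 2 points are reported with DBSCAN-style diameters
(singleton flags carry no meaningful diameter). The cited grid-based
formulation of the statistic is not fully specified in the source
literature available to us; this point-based realization preserves its
"local sum over global sum" semantics, and its null calibration is tested
directly (flagged fraction ≤ 6 % over hundreds of CSR fields).

## Coordinate-based colocalization

For each localization `i` of the reference species A, over bin radii
`r_k = k·r_max/10` (the `r = 0` bin is excluded by the `1/r²`
normalization):

$$D_{AA,i}(r_k) = \frac{N_{AA,i}(r_k)}{N_{AA,i}(r_{max})}\cdot
  \frac{r_{max}^2}{r_k^2},$$

`D_AB` analogously from cross-species counts; `S_i` is the Spearman
correlation of the two vectors (average ranks on ties), `E_i` the nearest
cross-species distance, and `C_i = S_i · e^{−E_i/r_{max}}`. The default
search radius is 80 nm — the scale of IgM nanocluster radii — with 10
bins (8 nm bins; at least 3 bins are required for the rank correlation to
mean anything).

Two conventions deserve justification:

* **Coincident cross-species points** are excluded from the count
  gradients but still define `E_i`. A cross-species localization at
  distance exactly 0 is, in a registered two-channel experiment, the same
  underlying emitter seen twice; including it in the counts provably
  breaks the identical-channel calibration (a point with same-species
  counts (0,0,0,1,…) acquires a cross-species gradient (1,1,1,2,…)/r²
  whose ranks invert). With the exclusion, `cbc(A, A)` returns exactly +1
  for every localization that has at least one same-species neighbor
  within `r_max` — the package's second calibration quantity.
* **Degenerate gradients** (no same-species or no cross-species neighbor
  within `r_max`, or a constant vector) leave Spearman undefined; such
  points are flagged and assigned `C_i = 0`, encoding "no colocalization
  information". Perfect exclusion (−1) is reachable through genuinely
  anti-correlated gradients, not through absence of neighbors.

Both directions (A as reference, B as reference) are computed and
reported separately by the pipeline — they answer different questions
when the two species have different cluster structure — and the
directional medians can differ appreciably, so condition comparisons
either fix a direction or average the two.

## Single-particle tracking

Detections in consecutive frames are linked when they are mutual nearest
neighbors within `max_disp`; there is no gap closing (a missed frame ends
the track) and tracks shorter than 10 frames are discarded. This is the
simplest defensible linker; rather than reproduce an unpublished
assignment algorithm, we validate it against synthetic ground truth
(≥ 95 % correct links when nearest-neighbor spacing exceeds
`5·√(4·D·dt)`). On crowded fields it fragments crossing trajectories
rather than guessing — fragments are cheap, wrong links poison the
diffusion estimate.

The time-averaged MSD uses overlapping pairs up to lag `⌊length/2⌋`, and
`D` is `slope/4` from an OLS line through the first 4 lags with a free
intercept. Four lags balance bias and noise; the free intercept absorbs
the static localization error (expected intercept `4σ_loc²`), so the
error magnitude need not be known. Non-positive slopes are floored at
`D = 10⁻⁶ µm²/s` and flagged; the floor does not move population medians
because it only relabels the already-lowest tail. The frame interval
defaults to `dt = 0.05 s` (20 frames/s). Parameter recovery is tested at
`D ∈ {0.005, 0.02, 0.08} µm²/s` with 1000 tracks of 200 frames and a
20 nm localization error: medians must land within 10 % of truth.

## The synthetic-data generator

The generator is a first-class module, because every downstream claim is
validated against it.

* **Cluster model: Thomas process.** Cluster centers uniform, Poisson
  cluster sizes, isotropic Gaussian offsets. Chosen over hard discs or
  other morphologies because its Ripley K has a closed form,
  `K(r) = πr² + (1/κ)(1 − e^{−r²/4σ²})`, giving an independent oracle;
  with a uniform background fraction `b` the field is a superposition and
  the excess term scales by `(1−b)²` (implemented in
  `thomas_k_theoretical()`). Offsets are wrapped toroidally by default so
  the process is stationary on the torus and the toroidal K estimator is
  exactly comparable to the closed form; `wrap = FALSE` instead resamples
  offsets into the region, keeping edge clusters intact in the Euclidean
  metric — the right choice for CBC work, where a wrap-split cluster
  would strand its edge members without neighbors.
* **Blinking.** Geometric number of appearances per molecule (memoryless,
  only the mean matters to the duplicate/merge logic), in frames drawn
  uniformly without replacement; per-blink uncertainty log-normal
  (positive by construction, matching typical SMLM uncertainty
  distributions). Because blink frames are scattered in time, gap-0
  merging deliberately cannot reconstruct molecule counts — count
  recovery is tested with the gap opened up on sparse fields.
* **Coupling.** A fraction of species-B molecules is relocated onto
  randomly chosen species-A positions plus Gaussian jitter, recording the
  partner identity. The jitter scale used in the direction-of-effect
  tests is 10 nm — molecular-association scale. Median CBC must rise
  monotonically over coupling fractions {0, 0.3, 0.6, 1}.
* **Nuisances.** Stage drift (linear or random-walk paths, pinned to zero
  at frame 0), fiducial beads localized in every frame of both channels
  with a minimum pairwise separation, and polynomial channel
  misalignment of degree 1 or 2 (invertible to < 0.1 nm by fixed-point
  iteration).

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: camera-frame formation (PSF shape,
Poisson shot noise, EM gain), fluorophore photophysics beyond the blink
count (no dark-state kinetics, no photobleaching gradients), 3-D effects,
inhomogeneous labeling efficiency, and cell-shaped (non-rectangular)
observation windows. Absolute values of clustering statistics on real
data also depend on label stoichiometry and multi-blinking left after
merging; with the default gap-0 merge, blink-level multiplicity remains
in the data and inflates the Hopkins index relative to molecule-level
truth, which is why cross-condition *directions*, not absolute values,
are the validated quantities.

## Scenario defaults and problem sizes

The end-to-end scenario simulates a 4 × 4 µm membrane patch with 60
clusters of ~30 molecules (σ = 60 nm, 20 % background) per channel, 20 %
cross-species coupling, 3 blinks/molecule over 2000 frames, 0.1 nm/frame
random-walk drift, 3 fiducials, and a (+30, −10) nm channel offset; SPT
simulates 60 molecules at D = 0.02 µm²/s over a 10 × 10 µm field (sparse
labeling, as in a tracking experiment). These sizes were chosen so that a
full scenario, the complete test suite, and the calibration script each
run in minutes on a single core while leaving every statistic's sampling
error well inside its test tolerance; the test files state the exact
sizes used per check (e.g. 100 CSR fields of n = 2000 for the Hopkins
calibration, 50 replicate Thomas fields for the K-function envelope,
1000 tracks per diffusion recovery point).

## Known limitations

* All statistics are 2-D; membrane topography is ignored.
* The Hopkins index is reported without a significance envelope; compare
  conditions with replicate spreads (as `compare_conditions()` does), not
  against 0.5 alone.
* The Getis threshold is Monte-Carlo and therefore seed-dependent at the
  margin; the seed is an explicit argument and is recorded in scenario
  outputs.
* CBC medians sit on a spike at 0 when many localizations are degenerate
  (sparse fields relative to `r_max`); the degenerate fraction is part of
  the result object and should be reported alongside the median.
* `couple_fields` models association by relocation, not by a joint
  generative model of co-clustering; coupling fraction and jitter are
  phenomenological knobs.
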