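---
title: "nucratio: methods, parameter choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nucratio: methods, parameter choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

`nucratio` quantifies how strongly a green fluorescent fusion reporter
(canonically EGFP-YAP) partitions into the nuclei of endothelial cells,
using a red histone-fusion marker (H2B-mCherry) as both the nuclear
mask and a ratiometric denominator. The modelling assumptions are:

1. **The red channel delimits the nucleus.** H2B is chromatin-bound, so
   thresholding red gives a nuclear mask independent of the reporter.
   Masking never consults the green channel (and a test asserts this).
2. **Mean pixel intensity is the unit of measurement.** All statistics
   are unweighted arithmetic means over mask voxels, even on
   anisotropic grids. Volume weighting is deliberately not offered: the
   quantity mirrored is "average pixel intensity per nucleus", and
   mixing conventions would make values incomparable.
3. **Ratios cancel nuisance gain.** The green/red nuclear ratio is
   invariant under any common gain (depth attenuation, laser drift,
   equal-channel bleaching). Green-only gain scales it linearly. The
   N/C ratio, a green/green quotient, is additionally invariant under
   green-only gain. These are exact algebraic facts and are enforced as
   property tests rather than assumed.
4. **No bleaching correction is applied to intensities.** Bleaching is
   handled only implicitly: by the co-measured red denominator in
   ratios, and by track-level red normalisation in time-lapse traces.

Three per-cell statistics, plus one normalisation:

* `ratio_3d` — mean green over all nucleus voxels / mean red over the
  same voxels.
* `ratio_2d` — the same quotient restricted to the central plane,
  defined as the rounded z-centroid of the nucleus (ties at .5 go to
  the lower plane). The 2D measurement reuses the 3D mask's plane
  rather than re-thresholding per plane; the alternative was
  underdetermined and re-thresholding would let the green-independence
  guarantee silently differ between 2D and 3D.
* `nc_ratio` — computed strictly in 2D at the plane of a supplied cell
  outline, because cytoplasm outlines are drawn on single planes; the
  cytoplasm region is the outline interior minus the nucleus mask at
  that plane, guaranteed disjoint from the nucleus.
* `da_norm` — nuclear green mean divided by the mean of `n_ref`
  dorsal-aorta reference nuclei from the same embryo (`n_ref = 6` by
  default, minimum 3). Reference cells are taken in ascending
  `cell_id` order: the original selection rule was not recorded, so the
  package uses the one deterministic rule that is reproducible from the
  data alone, and records the chosen cells in the output attributes.

Undefined ratios (zero denominators, empty planes) raise errors at the
single-cell level and become explicit `NA`s in tables — never
infinities or silent zeros.

## Segmentation conventions

* Thresholding: Otsu (256 bins) on the **nonzero** red histogram by
  default, or an absolute threshold for reproducibility. Otsu needs a
  background mode to separate; on synthetic images with a literally
  zero background the nonzero histogram contains only nuclear voxels
  and Otsu would split the nuclei themselves. The generator therefore
  exposes a `background` floor (expected counts added to both
  channels); the bundled pipeline config uses `background = 4` with
  Otsu, while exact-recovery tests use `background = 0` with an
  absolute threshold at half the nuclear red level.
* Connectivity is 26 in 3D and 8 in 2D; components smaller than
  `min_volume = 30` voxels (≈ 2.7 µm³ at the default voxel size) are
  removed as speckle.
* Labels are assigned in descending component size, ties broken by the
  lexicographically smallest (min z, min y, min x) of the component —
  fully deterministic, so masks can be compared across runs.
* Touching nuclei are **not** split (no watershed): the measured cells
  are well-separated by design, and the generator enforces
  non-overlapping nuclei (hard rejection sampling, up to 100 attempts,
  then an error naming the colliding cells).
* All voxel coordinates in this package are 1-based, matching R array
  indexing. Polygon membership uses pixel-centre containment: a pixel
  belongs to an outline iff its centre lies strictly inside the
  polygon (even-odd rule).

## The synthetic embryo: what it does and does not emulate

`generate_stack()` renders spherical nuclei (in micrometre space;
ellipsoids on the anisotropic grid, default voxel 1.0 × 0.3 × 0.3 µm —
typical confocal z/xy anisotropy) at two anatomically inspired sites: a
horizontal-myoseptum band of PL-class nuclei and a ventral row of
DA-class reference nuclei, the DA row staggered half a slot so the rows
interleave. Each cell carries uniform nuclear red (`red_level`, default
200 expected counts), uniform nuclear green `c_nuc = k · c_cyto` with
the partition `k ~ U(k_min, k_max)` (default 0.5–3, spanning
cytoplasmic to strongly nuclear reporters), and a spherical-shell
cytoplasm of thickness 2 µm at `cyto_level` (default 100). Defaults put
nuclear photon counts in the 100–600 range, where Poisson relative
error per nucleus mean is a fraction of a percent — the regime the
recovery criteria assume. Noise is Poisson on the expectation image;
time-lapses add per-frame drift (voxels/frame in y, x), per-channel
exponential bleaching `exp(-b·f)`, and scripted divisions (parent
replaced by two daughters offset along x with volume-conserving radii).

Deliberately **not** modelled: PSF blur and spectral bleed-through (no
optics simulation), partial-volume effects at nucleus boundaries
(rendering is binary per voxel centre), read noise, vessel lumens,
cytoplasm shape variability (the real cytoplasm is highly variable; the
shell is the simplest testable stand-in), and nucleus contact. A green
test therefore establishes that the *measurement chain* is correct on
its stated model — exact ratio recovery without noise, <2% cohort bias
under Poisson noise — not that segmentation would survive blurred,
touching nuclei in real data. Shells may overlap each other in dense
placements (only nuclei are collision-checked); cytoplasm-accuracy
tests use sparse placements where shells stay disjoint.

## Tracking

Frame-to-frame linking is greedy mutual-nearest-centroid in physical
(µm) coordinates: candidate links are taken in ascending distance
(ties: ascending label, then track id), capped at `max_displacement`.
Greedy linking was chosen over global assignment because the cell
densities involved are tens of nuclei at most, and exact, documented
tie-breaking matters more here than assignment optimality; the
interface would admit a Hungarian upgrade without contract changes.
`max_gap = 1` frame by default: at 20–22-minute sampling intervals,
longer gaps are biologically ambiguous.

Division handling needs one subtlety: after a division the parent's
nearest neighbour is usually one of its own daughters, so the parent
would simply continue into it. After matching, any track whose previous
position has two candidate nuclei within `max_displacement` — its own
match plus an unmatched newcomer, or two unmatched newcomers — is
re-interpreted as a division: the track ends and both nuclei start
daughter tracks with `parent_track_id` set. The division radius equals
`max_displacement` (one parameter, testable). Only one generation of
lineage is recorded.

Traces normalise per-frame green by the *track-level mean* red, so a
common gain cancels across the trace while genuine green dynamics
survive; if red itself varies, a green-equals-red trace equals
`red(f)/mean(red)` — a documented consequence of the definition, not a
bug.

## Spot detection

Laplacian-of-Gaussian at scale `sigma = (diameter/2)/sqrt(3)` (the 3D
blob-matching scale), computed as an anisotropy-aware separable
Gaussian followed by a physical-units Laplacian, response
`-sigma² ∇²`. Local maxima (strict, 26-neighbourhood) are kept above a
threshold expressed relative to the maximum response (default 0.1),
making counts invariant under global gain — the "quality" threshold of
the original commercial tool is unrecoverable, and relative thresholds
transfer across gain settings. Greedy suppression enforces a minimum
separation of one `diameter`, in descending response order with
coordinate tie-breaks. Maxima within one sigma of the stack border are
excluded: the replicate-boundary Laplacian manufactures spurious maxima
on border planes (observed directly below deep nuclei in testing).

## Statistics

* SEM uses the sample standard deviation (n−1); `n = 1` reports SEM 0
  with a warning.
* t-tests: Student (pooled) by default, Welch by flag; raw-sample and
  summary-statistics (mean, SEM, n) modes, the latter so printed group
  summaries can be checked without raw data. Degenerate zero-SEM
  summaries resolve to p = 1 (equal means) or a p → 0 flag (distinct
  means).
* Correlation: sample Pearson r, 95% CI via Fisher z
  `tanh(atanh(r) ± 1.96/√(n−3))`, p from the t-distribution with n−2
  df, ordinary least-squares slope/intercept.
* Significance stars: two schemes. The default `conventional` scheme
  (strict `<` at 0.05/0.01/0.001/0.0001) is the one every published
  (p, stars) pair in the source legends actually follows — e.g.
  0.0036→\*\*, 0.0006→\*\*\*, 0.0157→\*. The `gp` scheme implements the
  GraphPad-style thresholds printed in the methods text with `≤`
  semantics (0.0001/0.0002/0.0021/0.0332); the printed "0.332" is read
  as the evident typo for 0.0332. Both are available and neither is
  silently "fixed"; the default follows demonstrated usage.
* Graft-size classes overlap as published at a span of 2 somites
  ("small 1–2", "medium 2–3"); span 2 classifies as medium and emits a
  warning surfacing the overlap instead of hiding it.
* No multiple-testing correction and no nonparametric tests, matching
  the statistical repertoire being reproduced.

## IO and reproducibility

Stacks are written as uncompressed OME-TIFF (pages z-fastest, then
channel, then time; 64-bit float so round-trips are bit-exact) with
dimension sizes and physical voxel sizes in the OME-XML header; the
reader also accepts 8/16-bit TIFFs from other writers given explicit
size/voxel overrides. The codec is implemented in-package because the
target environment provides no R TIFF reader; tests validate it
against an independent external TIFF implementation. Configuration
files are JSON; every output table carries a provenance header
(package version, seed, config hash, inputs), and identical
config + seed reproduce byte-identical table bodies. All generator and
pipeline randomness flows from a single integer seed.

## Known limitations

* Segmentation assumes separated nuclei; contact cases are out of
  scope by design and untested.
* The 2D ratio inherits the 3D threshold; on strongly z-attenuated real
  data a per-plane threshold could differ.
* The N/C ratio depends on user-supplied outlines; there is no
  automatic cytoplasm segmentation, faithful to the manual original.
* Lineage depth is one division; entries/exits during gaps longer than
  `max_gap` fragment tracks rather than bridging them.
* The acceptance layer reproduces published statistics whose inputs are
  printed; cohort-level values measured from real embryos are not
  recomputable without the deposited source data.
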