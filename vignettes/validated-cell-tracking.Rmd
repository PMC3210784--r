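---
title: "Validated overlap tracking of unlabeled cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validated overlap tracking of unlabeled cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackvalidatr)
library(dplyr)
```

## The problem

Time-lapse microscopy of unlabeled, adherent cell cultures produces
stacks of grey-value images in which every cell must be found and then
followed from frame to frame, through its divisions, to reconstruct
complete cell lives and genealogic trees. No detector or tracker is
error-free, and tracking has a particularly unforgiving error
propagation: a single missed or merged cell corrupts every genealogic
statement downstream of it. With a per-frame success probability $p$
and independent errors, a path of $n$ frames survives intact with
probability $p^n$ — at $p = 0.95$ and $n = 50$ that is only
`r round(100 * path_survival_probability(0.95, 50), 1)`%. Good
detection alone therefore cannot produce trustworthy lineages.

trackvalidatr takes the position that tracking output must be
*validated*: systematically searched for every structural error
pattern, with whole cell lives — paths from one mitosis to the next —
as the unit of acceptance or rejection. The result is a smaller but
highly reliable set of complete paths, from which population
statistics (cell-cycle times, division symmetry, growth and
confluency curves) can be extracted automatically.

## Pipeline

1. **Pre-processing** (`preprocess_frame()`): uneven illumination is
   removed with a high-pass filter (raw minus Gaussian-blurred copy,
   `sigma` well above the cell diameter, default 25 px), then grey
   values are mapped linearly to 8 bit.
2. **Detection** (`detect_cells()`): Otsu's global threshold on the
   per-frame histogram; pixels strictly brighter than the threshold
   are foreground. Erosion (disc, radius 1) separates tiny false
   connections, dilation (disc, radius 1) fills holes, and regions
   below `min_area` (default 50 px) are removed. Foreground
   connectivity is 8-connected throughout the package. Each remaining
   region — a detected cell — is labelled 1..n in raster-scan order.
3. **Features** (`extract_features()`): centroid, area (pixel count),
   mean grey value, and compactness $C = 4\pi A / P^2$, where $P$ is
   the length of the outer boundary contour. $C = 1$ for a perfect
   circle. The contour length uses Moore-neighbour tracing with the
   corner-corrected chain estimator
   $P = 0.980\,N_a + 1.406\,N_d - 0.091\,N_c$, which keeps the error
   on digitized circles below about 1% (a radius-50 disk scores
   $C \approx 1.01$).
4. **Overlap linking** (`pairwise_overlaps()`, `link_cells()`,
   `build_path_fragments()`): a cell in frame $t$ and a candidate in
   $t+1$ are scored by forward overlap (intersection over the cell's
   area) and backward overlap (intersection over the candidate's
   area). Fragments grow only through links that pass both thresholds
   (`t_fw = t_bw = 0.3` by default) *and* are unambiguous: as soon as
   more than one concurrent overlap occurs on either side, path
   construction aborts there. All candidate continuations at abort
   points are stored in a symmetric fragment adjacency relation — a
   starting hypothesis, not a lineage claim.
5. **Mitosis detection** (`detect_mitoses()`): a division must show a
   Y-shape (exactly two successor fragments, each with this fragment
   as its only candidate predecessor) *and* the morphological pattern
   of a dividing cell — it contracts, rounds up and brightens. The
   pattern is scored as the multivariate-normal density of the mean
   difference vector (speed, area change, brightness change,
   compactness change) of the parent's last $k = 2$ steps, under a
   model fitted on known divisions; the detection threshold `t_mit`
   must be exceeded.
6. **Validation** (`validate_tracks()`): termini are explained by the
   error decision tree in a fixed order from conclusive to
   inconclusive: movie boundary, image border (margin 30 px,
   roughly 50 µm at 1.6 µm/px), merged cells (reversed-Y: several
   fragments ending in one successor), mitosis, vanished cells
   (recovered with a local Otsu threshold in a window around the lost
   terminus), cell death (sustained terminal shrinkage; heuristic),
   debris (sudden appearance, span of one or two frames, fast drift),
   and finally *unresolved*. A Y-split of a fragment that itself arose
   from a merge is a separation of merged cells, never a mitosis.
   Accepted output consists solely of complete paths — chains born at
   an accepted mitosis and ending as the parent of one, bridged only
   across recovered dropout gaps, and touching no merge, border or
   unresolved terminus. If in doubt, the path is excluded.
7. **Evaluation** (`match_detections()`, `classification_counts()`,
   `genealogy_error_rates()`): detection is scored per frame with
   dual-overlap matching (a detection and a reference cell must
   overlap each other by more than 30%, one-to-one); FAR = FP/(TP+FP)
   and FRR = FN/(TP+FN). Tracking is scored by *trustworthiness*,
   100 × correct/returned, for mitoses and for complete paths, and by
   genealogic degree-of-relation errors. `naive_track()` provides the
   unvalidated baseline: backward greedy linking by largest overlap,
   whose Y-junctions must be taken at face value as mitoses.

## The synthetic-data generator

Real reference data with manually corrected, pixel-exact lineages are
expensive; the package therefore ships a seeded simulator
(`simulate_movie()`) whose ground truth (masks, cell registry,
lineage, event log) drives calibration, testing and evaluation.

The generator's defaults mirror the culture conditions the method was
designed for: 1376 × 1038 px frames at 1.6 µm/px every 15 minutes,
282 initial cells, bright elliptical cell bodies (area roughly
100–3000 px; radius 12 ± 2.5 px) on a darker background (grey 120 vs
40, noise SD 5, optional linear illumination ramp), Brownian motion
(1.5 px/frame) with optional drift, and cell-cycle times from a
truncated normal (mean 720 min, SD 180 min, floor two frames). A
soft contact repulsion keeps adherent neighbours from interpenetrating.
Divisions follow the characteristic pre-mitotic pattern over two
frames — area shrinks by 25%, the aspect ratio relaxes to 1, the
brightness rises by 30% — after which two round daughters (55% of
adult area, regrowing over a few frames) appear side by side inside
the parent's footprint, separated by a narrow cleavage gap. Newborn
pairs are exempted from motion and repulsion on their birth frame so
that the gap survives rasterization exactly once; afterwards normal
contact repulsion separates them.

All four error scenarios the validator must handle are injected by
count, so a test movie contains a known number of each: optical
merges (two cells steered into contact, held, then released), dropout
intervals (a cell's contrast reduced to a configurable fraction — at
0.35 it falls below the global threshold but stays recoverable by a
local one; at 0 it is invisible), border crossings (cells leave, and
optionally enter, through the image edge), and debris (small, fast,
linearly drifting blobs that are rendered but are not cells and never
appear in the truth masks).

What the simulator deliberately does **not** emulate: phase-contrast
optics (halos, shade-off), cell shape dynamics beyond ellipse jitter,
density-dependent area shrinkage (contact inhibition of cell size),
apoptosis, and 3-D culture. Tests passing on synthetic movies
therefore demonstrate the correctness of the algorithms under the
stated imaging model, not performance on any particular microscope's
data; on real images the detector's error modes (halos fusing cells,
focus drift) will be harsher, which is precisely why the validation
layer, not the detector, carries the reliability guarantee.

## Calibration of the mitosis model

`fit_mitosis_model()` runs the full detection/tracking pipeline on a
calibration movie, collects the terminal difference-vector windows of
fragments whose ends coincide with true divisions (matched by dual
overlap against the truth masks), and fits the multivariate normal to
them. Fitting on tracked rather than ground-truth features keeps the
model on the same scale as the vectors it later scores — detected
areas and preprocessed grey values differ systematically from their
ideal counterparts. The threshold `t_mit` is placed at the 5th
percentile of the training densities (95% recall); it is stored with
the model and serialized to JSON by `write_similarity_model()`. A
near-singular covariance receives a relative ridge of
$10^{-6}\,\mathrm{tr}(\Sigma)/n$ on the diagonal.

## Numerical and design choices

* **Connectivity** is 8-connected everywhere (labelling, overlap,
  contour tracing); it must be fixed project-wide or overlap counts
  and region areas disagree between modules.
* **Thresholding direction**: foreground is *strictly greater* than
  the Otsu threshold; ties in the between-class variance argmax are
  broken toward the lowest threshold.
* **Link tie-breaks** in naive tracking: largest intersection, then
  largest overlap ratio, then lowest label — deterministic.
* **Ambiguity floor** (`t_amb = 0.1`): concurrent overlaps with both
  ratios above 10% veto link uniqueness even when they fail the link
  thresholds. Fragment construction is meant to abort wherever more
  than one continuation is plausible; without the floor, a division
  whose two daughters straddle the 30% threshold can be silently
  traversed, which is exactly the error class validation exists to
  prevent. Purely incidental pixel-level contacts stay below the
  floor and do not shatter fragments.
* **Mitosis windowing**: $k = 2$ steps, matching the two-frame
  pre-mitotic pattern; fragments shorter than two steps cannot be
  scored and are conservatively never mitotic parents.
* **Merged beats mitosis** in the decision tree: a merge successor's
  later split is a separation, so such Y-junctions are removed from
  the mitosis list before assembly.
* **Merge rectification** by feature matching across a merge
  (`rectify_merges = TRUE`) exists but is off by default; re-assigning
  identities across a merge can introduce new errors, and the
  conservative default is detect-and-reject.
* **Degree of relation** counts mitosis events on the unique tree
  path: siblings and parent–child pairs score 1, first cousins 3;
  0 is reserved for unrelated cells, so the query cells must differ.
* **Life time** of a complete path is
  (death frame − birth frame) × frame interval, i.e. the span between
  the mitosis that created the cell and its own division; each sample
  is also stamped with its end time so confluency-driven prolongation
  is visible. Daughters for the signed sibling-symmetry difference
  are ordered by path id (the absolute difference is reported
  alongside).
* **Division probability** per window is
  100 × mitoses / mean per-frame cell count, window default 2 h.
  Histogram binning for life times defaults to Freedman–Diaconis.
* **FAR/FRR for detection** are defined as FP/(TP+FP) and FN/(TP+FN):
  true negatives are not enumerable for cell detection (there is no
  countable set of non-cells), and this choice makes a 95% detection
  rate correspond to FRR ≈ 5%.
* **Mitosis correctness tolerance** in evaluation is ±1 frame between
  a detected division and the matched true division.

## Problem sizes used in the test-suite

The packaged checks run on seeded simulations chosen to exercise each
claim at meaningful sample sizes: a 400² px calibration culture
(12 starting cells, 50 frames, ~60 divisions) for model fitting; a
640² px clean culture (40 cells, 40 frames) for detection quality,
where per-frame FAR and FRR stay within 5% and over 99% of true
regions are recovered; a 768 × 614 px error-injected benchmark
(50 starting cells, 150 frames, six merges, six dropouts, four debris
particles, border traffic) on which accepted complete paths are
≥ 95% correct while naive tracking scores strictly lower; and a 1280² px
unbiased culture (36 cells, 90 frames, ~1000 divisions) yielding over
300 accepted paths for the distribution-level no-bias check
(two-sample Kolmogorov–Smirnov against ground-truth life times,
α = 0.01).

## Known limitations

* The validator's recovery step searches backwards from lost
  beginnings only (joins to lost ends arise symmetrically); a gap
  longer than `max_gap` frames (default 4) is not bridged.
* Cell death has no dedicated detector in the source method; the
  terminal-shrinkage heuristic here classifies but never rescues such
  paths.
* `rectify_merges` uses greedy feature matching, not an optimal
  assignment, and is therefore kept off by default.
* Genealogy comparison requires a cell-level correspondence; cells
  the detector never matched count as missed relations, which is the
  conservative choice.
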