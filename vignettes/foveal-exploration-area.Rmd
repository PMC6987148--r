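---
title: "Foveal coverage analysis of free visual exploration data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foveal coverage analysis of free visual exploration data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Free visual exploration (FVE) — letting a participant look at natural-scene
pictures with no task — is a sensitive probe of spontaneous visuospatial
attention, and a standard tool for characterising hemispatial neglect after
right-hemispheric stroke. Conventional FVE indicators treat each fixation as
a point: the mean horizontal gaze position, the leftmost fixation, and the
per-half fixation counts and cumulative durations all summarise point
coordinates.

A fixation is not a point, though. Visual information is processed across
the fovea, roughly the central 1.5–2° of the visual field. Treating each
fixation as a disk of 1° radius and taking the union of those disks yields
the **visual exploration area**: the fraction of the picture that was
actually covered by foveal vision. Two behaviours that are identical in
fixation counts can differ sharply in coverage — twenty fixations piled onto
the same spot explore far less of a picture than twenty spread-out ones.
That distinction is clinically meaningful: neglect patients refixate nearby
locations far more often than controls, so their rightward surplus of
fixations does not translate into a larger explored area.

`fovarea` implements this coverage analysis together with the fixation
taxonomy it enables, the conventional indicators for comparison, the
group-level statistics, and a seeded synthetic-cohort generator so the whole
pipeline can be exercised and validated without patient data.

## The coverage model

The screen geometry fixes everything: a `width_px`-by-`height_px` picture
subtending `h_deg` × `v_deg` degrees of visual angle. With the defaults
(1,200 × 900 px, 27° × 21°, viewed at 68 cm) the vertical scale is
900/21 ≈ 42.86 px/°, so a 1° foveal radius is 43 px after rounding to the
nearest integer. The vertical axis is used for this conversion because it
reproduces the canonical 43-px radius; the horizontal scale (44.4 px/°)
would give 44 px. Both the radius in degrees and the geometry are
user-configurable, so the choice only matters for anisotropic pixels.

A coverage raster is a `height_px × width_px` binary matrix. Cell
`(row, col)` sits at pixel coordinates `(x = col, y = row)` (0-based,
origin top-left, no half-pixel offset) and is set to 1 iff its Euclidean
pixel distance to at least one fixation centre is **≤** the foveal radius —
a closed disk. Cells under several disks are counted once. The exploration
area of a region is

$$\mathrm{area}(R) \;=\; 100 \times
  \frac{\#\{\text{covered cells in } R\}}{W \times H}\,,$$

with the **total** matrix as denominator even for half-screen regions, so
`left + right = total` holds exactly and values are comparable across
regions. (A within-half normalisation is available behind
`within_half = TRUE`, off by default.)

Numerical choices worth stating explicitly, since the boundary behaviour is
conventionally under-specified:

* the distance test is a *closed* disk (`≤ r`); tangent cells count as
  covered. Open vs closed shifts areas by well under 0.01% of the matrix;
* fixation centres keep their fractional pixel coordinates — no snapping
  before the distance test, so sub-pixel eye-tracker output is honoured;
* disks are clipped at the matrix edge, and off-screen fixation centres
  (flagged, never dropped, at import) still stamp their in-bounds portion;
* the fast implementation stamps one bounding box per fixation; the test
  suite holds it cell-for-cell equal to a naive full-grid distance scan on
  hundreds of random configurations, and to the exact lattice-disk count
  (5,789 cells for r = 43 px) for an isolated interior fixation.

The **picture-wise** analysis builds one raster per participant × picture
and averages areas over pictures within participant; the **cumulative**
analysis pools all of a participant's fixations (e.g., 24 pictures) into a
single union raster. Pictures in the experiment roster on which a
participant produced no retained fixations contribute 0% to their mean.

## Fixation taxonomy

With disks in hand, fixations classify naturally:

* **single** — no other fixation of the trial (any temporal order) lies
  strictly within 2 r (2°) of its centre; its disk intersects no other disk
  with positive area. Strictness means exactly-tangent disks, whose
  intersection has zero area, stay single.
* **overlapping** — everything else; equivalently
  `n_overlap = n_total − n_single`.

Overlapping fixations subdivide in temporal order:

* **capture** — lands strictly within 1° of its *immediately preceding*
  fixation: a successive refixation, the oculomotor signature of impaired
  attentional disengagement;
* **re-capture** — not a capture, but within 1° of some temporally distant
  (non-adjacent) earlier fixation: a revisit, pointing at spatial working
  memory;
* **other** — overlapping by the 2° rule, yet not within 1° of any *prior*
  fixation (its near neighbours all come later, or it is the trial's first
  fixation). This residual class is kept explicit rather than silently
  merged into the other two.

Capture takes precedence when both rules match, being the more specific
one. Distances are computed in degrees with per-axis pixel scaling, because
both thresholds are stated in degrees and pixels are anisotropic. The 2°
overlap threshold and the 1° capture/re-capture threshold are deliberately
distinct parameters; `consistent_thresholds = TRUE` forces them equal
(threshold = 2 r), after which "other" survives only for fixations whose
near neighbours all lie in the future.

The clustering index is the **overlap proportion**, `n_overlap / n_single`
per region, computed per picture and averaged over the pictures where it is
defined (at least one single fixation); with no single fixations it is
missing, not zero. **Temporal dynamics** curves report, for each prefix
length k = 1..20, the percentage of capture (resp. re-capture) fixations
among a trial's first k fixations, averaged over pictures, then
participants; pictures contribute at every k up to their own fixation
count, and the ribbon is the between-participant standard error.

## Conventional indicators

For comparison the package computes the four standard FVE neglect metrics,
each per picture then averaged within participant: mean horizontal gaze
position (unweighted mean over fixations, in degrees from the picture
centre, negative = left; a duration-weighted variant sits behind a flag),
leftmost fixation, per-half fixation counts, and per-half cumulative
durations. The screen is split at column `width_px/2`; a centre exactly on
the split column counts as right (the tie rule is stated nowhere in common
practice, so it is fixed here and tested). Fixations are pre-filtered to
durations within [100, 2000] ms, inclusive on both ends — the conservative
reading of the usual "between 100 and 2,000 ms" phrasing — and the excluded
fraction is reported (pooled and per participant) rather than asserted.

Horizontal histograms use 2° bins anchored at −h/2; 27° does not divide
evenly by 2, so the final bin is truncated at +13.5° and off-screen
positions are clamped into the boundary bins, keeping the counts summing to
the number of fixations.

## Statistics

Group comparisons follow the standard FVE inferential pipeline on
per-participant averages: two-sided Welch t-tests (the unequal-variance
default; a pooled-variance Student flag exists) with Cohen's
r = √(t²/(t²+df)); balanced split-plot ANOVAs via `stats::aov()` with
`Error()` strata for 2 × 2 (group × screen half) and 2 × 2 × 2
(group × half × fixation category) designs; and Bonferroni-corrected post
hoc t-tests over all pairwise design cells (paired within a group,
independent across groups, multiplier = number of pairs). Effect size for
ANOVA effects is partial η² = SS_effect/(SS_effect + SS_error), labelled as
partial; generalized η² is reported alongside. Only balanced designs are
supported — unbalanced split-plot sums-of-squares questions are out of
scope, and 2-level within factors make sphericity corrections moot. The
F table reports (df_effect, df_error), i.e., (1, 33) for a 20 + 15 cohort.

## The synthetic cohort generator

No public FVE patient dataset exists to test against, so the package ships
a generative emulation of the two cohorts. It is an emulation of observed
summary statistics, not an inference: per trial, per-half fixation counts
are Poisson draws around per-group targets (controls 10.495 left / 11.012
right per picture; patients 3.848 / 13.859); the first fixation starts near
the screen centre (the fixation-cross constraint, SD 0.5°); each subsequent
fixation is, with probability `p_cap`, placed uniformly within 1° of the
most recent earlier fixation of its designated half, with probability
`p_rev` within 1° of a randomly chosen temporally distant earlier fixation
of that half, and otherwise drawn fresh from a bivariate normal centred
horizontally at the group's gaze bias (+0.231° controls, +3.652° patients),
truncated to the designated half, with SD spanning the half (6.75°
horizontally, 5.25° vertically). Durations are truncated normal within
[100, 2000] ms, with group means (133 ms controls, 178 ms patients) chosen
so per-half cumulative durations land near the observed group values;
onsets accumulate durations plus a nominal 30-ms saccade gap.

Two structural choices deserve their rationale. Refixation references are
restricted to the fixation's own designated half: refixations happen where
exploration currently dwells, and cross-half references would dilute the
count-driven spatial asymmetry that carries the group difference. And the
forced central first fixation is never a refixation reference — it is an
experimental artefact, not an exploration locus, and chains seeded from it
would inject central mass into both halves. With these, the recovered
patient mean gaze position lands within a few tenths of a degree of the
+3.652° placement centre by construction.

The per-group-half refixation probabilities (controls 0.18/0.20 both
halves; patients 0.12/0.10 left, 0.30/0.25 right) were derived once from
the observed per-picture capture and re-capture means and the patients'
right-half overlap excess. The generator records its own placement decision
per fixation (`gen_class`), so classifier sensitivity is measurable against
ground truth: every generated capture-type placement must be detected as
overlapping, and is recovered as capture or re-capture depending on whether
its same-half reference was the global immediate predecessor.

What the emulation deliberately does **not** model: picture-content
saliency (real fixations cluster on objects and faces), main-sequence
saccade dynamics, drift or calibration error, vertical asymmetries, and
between-picture heterogeneity. Passing parameter-recovery tests therefore
shows that the *pipeline* is correct and sensitive to the modelled effects,
not that real patient data would produce these exact numbers — with real
scene-driven clustering, overlap proportions would differ from the
generator's spatially homogeneous collisions.

## Validation strategy and problem sizes

The test suite pins every operation to an independent oracle: rasterization
against a naive full-grid per-pixel scan (50+ random geometries up to
200 × 200 with up to 20 fixations), the taxonomy against a brute-force
double-loop re-implementation of its definitions, temporal dynamics against
closed forms (all-coincident trials give a capture curve of 100 (k−1)/k)
and explicit recounts, ANOVA sums of squares against textbook split-plot
formulas, and the Welch test against its empirical type-I error (10,000
null pairs at n = 15 vs 20, expected 0.05 ± 0.01) and a 10⁵-shuffle
studentized permutation oracle. The permutation check is asserted at 0.01
absolute agreement: the Welch p is asymptotic while the permutation p is
exact, so at these sample sizes a small systematic gap remains on top of
the ~0.0015 Monte-Carlo standard error; demanding pure Monte-Carlo
agreement between the two would be comparing different tests.

Cohort-level checks run the full pipeline on the default two-group cohort
(20 + 15 participants × 24 pictures, ~18,000 fixations) at fixed seeds and
assert the qualitative structure the analysis exists to detect: patients'
rightward gaze shift recovered within ±0.5°, overlap proportion maximal in
the patients' right half, patients' left-half exploration area below the
controls'. `scripts/acceptance.R` recomputes all headline quantities from
scratch at an arbitrary seed.

## Known limitations

* Only balanced split-plot designs; participants with missing within-cells
  are rejected, not imputed.
* The half-screen dichotomy is fixed (no vertical splits, no annular
  regions); graded attention maps (Gaussian-weighted, duration-weighted)
  are out of scope.
* The raster is memory-naive (one logical matrix per trial) — fine at
  1,200 × 900, not intended for 4K-and-beyond stimulus grids.
* Event detection (raw samples → fixations) is upstream of this package;
  input is an already-parsed fixation table.
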