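---
title: "Detecting ureteral stent encrustation by 3D morphological analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ureteral stent encrustation by 3D morphological analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The clinical question and the model behind the pipeline

An indwelling double-J ureteral stent mineralises with time. Whether the
bright material seen around a stent on CT is *encrustation* (deposit grown
on the stent wall, which complicates removal) or a *residual stone fragment*
(which merely touches the stent) changes the treatment plan. Both have
attenuation overlapping the stent's own, so neither thresholding nor a 2D
slice-by-slice view separates them reliably.

`stentcheck` frames the problem geometrically. A stent is a thin curved tube
of roughly constant radius; every stent pathology in scope expresses itself
as a *radial* deviation from that tube. The pipeline therefore reduces the
volume to the tube's intrinsic coordinates — arc length along the centerline
and angle around it — and reads the pathology off the radius function
r(s, θ):

* clean stent: r(s, θ) ≈ r₀, flat up to discretisation;
* residual stone: one contiguous interval in s with a large excursion
  (a sphere pressed against the wall);
* encrustation: many short intermittent excursions scattered along s
  (deposits nucleate at multiple sites on the wall).

Everything before the classification exists to compute r(s, θ) robustly
from a voxel mask: connected-domain filtering finds the tube, thinning and
spline fitting recover s, perpendicular re-slicing and the polar transform
recover θ and r.

## Stage by stage

### Segmentation providers

The 2D per-slice detection that a trained network would supply is behind a
provider interface: `threshold_segment()` (default window 300–3000 HU) or
`import_mask()` for external model output. A threshold deliberately
over-segments — stones, bone and the stent share the window — because the
downstream 3D filtering, not the segmenter, is what isolates the stent.
Networks themselves are out of scope: they are untrainable and unverifiable
without a clinical dataset, and the package's verifiable substance lies
downstream of the mask.

### Connected-domain analysis

`label_components()` is the classic two-pass raster scan: the first pass
labels each foreground voxel from its already-visited neighbours and records
label equivalences; the second resolves each voxel to its equivalence-class
minimum. Equivalences are held in a union-find table with path compression —
same result as an explicit equality list, near-linear time. Adjacency is
selectable (6, 18, 26); the default for stent work is 26 because a thin
tilted tube often connects only corner-to-corner between slices. The
independent oracle in the test suite is a breadth-first flood fill written
directly from the adjacency definition; the two must produce identical
partitions on random volumes.

`select_stent_component()` keeps the component with the greatest z-extent
among those with z-extent ≥ 100 mm and elongation ≥ 3 (ties: more voxels,
then lower label). A double-J stent spans kidney to bladder (≈ 200–300 mm of
anatomy, ≥ 100 mm of z even when coiled), while fragments and bone blobs are
compact; both filters are configurable. `fill_gaps()` runs first, bridging
axial dropouts of at most 5 slices when the flanking in-plane centroids are
within 10 mm, inserting linearly interpolated disks. Bridging before
labeling matters: an unbridged gap would split the stent into two components
that each might fail the length filter.

### Centerline: thinning, ordering, fitting

`thin_to_skeleton()` peels boundary voxels in six directional subiterations.
A voxel is deletable when it is a *simple point* — its removal provably
preserves local topology, tested with the standard two-condition
characterisation (one 26-connected foreground component among the 26
neighbours; one 6-connected background component in the 18-neighbourhood
touching a face) — and not a curve endpoint (≤ 1 foreground neighbour).
Deletions are sequential with re-checking, which guarantees topology
preservation without a certified parallel template set. Two numerical
choices harden this against degenerate inputs:

* within each directional pass, voxels are processed in two checkerboard
  subfields (by parity of x+y+z). Without this, a bar of even width that is
  exactly symmetric about the grid collapses lengthwise: every voxel of the
  bar is a frozen border candidate and diagonal adjacency keeps each
  deletion simple, so a single pass can eat the whole bar. (The widely used
  reference implementation of this algorithm family returns an *empty*
  skeleton on such bars; the subfields make the degenerate case behave like
  the generic one.)
* the phantom generator never places a tube in the exactly grid-symmetric
  position, for the same reason a scanner never does.

`order_skeleton()` must turn the skeleton voxel set into an ordered path,
which the curve fit needs but thinning does not provide. The centerline is
taken as the longest geodesic path (tree diameter, Euclidean edge weights)
between two endpoints — for a simply connected tube the skeleton is a tree
and its diameter runs end to end. Side branches are thinning artefacts over
wall bulges; branches whose depth from the path is below `prune_len`
(default 5 voxels) are dismissed, deeper ones raise an error that reports
the endpoint count. The pipeline escalates `prune_len` by doubling (up to
60) when that error occurs, because an attached stone reliably grows a
medial branch of roughly its own radius. The superior (greater z) endpoint
is taken as the path start by convention.

`fit_curve()` fits each coordinate against the chord-length parameter with a
cubic smoothing spline. The default (`smoothing = "auto"`) fixes the
equivalent degrees of freedom at n/8, clamped to 8–24: enough for double-J
curvature, too stiff to follow voxel jitter. Generalised cross-validation is
available but not the default — skeleton jitter is not independent smooth
noise, and GCV responds by choosing ≈ n degrees of freedom, which turns into
tangent errors of tens of degrees and obliquely cut sections downstream.
`smoothing = 0` gives an exact natural-spline interpolant (used by tests
that need machine-precision reproduction).

### Perpendicular re-slicing

`extract_sections()` samples the mask by trilinear interpolation on square
patches (default 20 mm at 0.15 mm pitch) perpendicular to the fitted
tangent, at arc-length-uniform stations (default 1 mm). The in-plane frame
is u = normalize(t × ẑ), v = t × u, falling back to t × x̂ for near-vertical
tangents and to the previous section's frame for a degenerate tangent —
deterministic and continuous along the stent. The first and last 3 mm of
arc are not sampled: a plane at the very tip cuts the rounded end cap into a
crescent whose small area would otherwise contaminate the area statistics.
Area is foreground pixel count × pixel area after thresholding the
interpolated patch at 0.5.

The patch pitch default of 0.15 mm is finer than the in-plane voxel pitch
because the classifier thresholds *relative radius*: at a 2.5 mm tube
radius, a one-pixel rim artefact at 0.25 mm is already a 10 % radius error,
uncomfortably close to the 15 % elevation threshold, while at 0.15 mm it is
6 %.

`detect_area_anomalies()` implements the sorted-jump boundary rule: areas
are normalized by the sequence median, sorted, and the first adjacent sorted
pair that differs by more than `jump_threshold` (default 0.3) *and lies
above the median* defines the boundary; sections at or above the boundary
form the preliminary anomaly segments. The above-the-median guard is this
package's refinement: anomalies of interest only ever increase area, and
without the guard a mild low-area outlier would put the boundary below the
bulk and flag the entire stent.

### Polar profiling and classification

`polar_transform()` reduces a section to radius-versus-angle: 64 uniform
bins over [0, 2π), radius = distance from the foreground centroid to the
outermost foreground pixel in the bin. Centroid centring makes the profile
translation-invariant; bins that receive no pixel (possible for coarse
patches) are flagged and excluded rather than reported as zero radius.

`profile_features()` smooths each profile with a 3-bin circular median
filter (≈ 17°) before thresholding. The outermost-pixel statistic is an
extreme-value estimate and inherits the voxel grid's rim aliasing as 1–2-bin
spikes; the filter removes those while leaving real bumps (tens of degrees)
intact. The baseline radius is the median over all bins of the sections
*not* flagged by the area rule (falling back to the global median), a bin is
elevated above baseline × 1.15, a section is elevated if any bin is, and
elevated sections are grouped into maximal consecutive runs. Single-section
runs whose peak elevation is below the residual-stone magnitude (0.5) are
dropped as noise: a real deposit shorter than the 1 mm section spacing with
near-threshold amplitude is not a clinically meaningful finding, and such
blips otherwise convert clean cases into false positives through the
ambiguous branch below.

`classify_anomaly()` encodes the morphological contrast:

| pattern | rule (defaults) | class |
|---|---|---|
| no elevated run | — | clean |
| ≤ 2 runs, longest ≥ 8 % of sections, peak ≥ +50 % | concentrated, strong | residual stone |
| ≥ 3 runs, each ≤ 5 % of sections | intermittent, short | encrustation |
| anything else | ambiguous | encrustation |

Ambiguity resolves to encrustation deliberately: the costly clinical error
is attempting outpatient removal of an encrusted stent, so uncertain cases
should flag for review. All six thresholds live in
`detection_thresholds()`, are configurable, and are serialized into every
report. The final verdict (`decide_case()`) gives encrustation precedence
over residual stone; a case with no surviving anomaly is negative.

In `run_case()` the area rule localizes and the polar analysis decides: if
the polar classification is clean the case is negative regardless of area
segments, and if the polar analysis finds a pattern that the sorted-jump
rule missed (graded low bumps produce a smooth ramp in the sorted area
sequence with no single jump), the elevated runs themselves become the
reported segments.

## The phantom generator: what it emulates and what it does not

`render_phantom()` rasterises an analytic scene, so the ground truth —
centerline, class masks, anomaly arc-intervals — is exact by construction:

* grid 96 × 96 × 120 voxels at (0.7, 0.7, 1.25) mm: routine abdominal CT
  resolution, anisotropic on purpose so that no stage can confuse voxel and
  physical units;
* tube radius 2.5 mm along a gentle helix (radius 10 mm, one turn over
  ≈ 134 mm of height, seeded phase), giving sustained out-of-plane tilt of
  ≈ 26° — enough that axial areas are inflated ≈ 11 % and perpendicular
  re-slicing does real work; `straight`, `tilted` and `piecewise_j`
  centerline families are also available;
* HU palette: background 20, stent 900, stones and encrustation 700, bone
  1100, Gaussian noise σ = 15 added last. Stent and stone attenuations
  deliberately overlap within one threshold window so connected-domain
  filtering, not windowing, must separate them;
* encrustation: 4–7 wall bumps, radial height 1.6–2.5 mm, angular width
  80–120°, arc length 3–5 mm, stratified along the stent;
* residual stone: one sphere of radius 6.5–7.5 mm at the wall. At
  `offset_mm = 0` ("touching") the centre is pulled in by half the largest
  voxel dimension: an exact point tangency does not survive voxelisation
  (the two voxel sets can fail to be 26-adjacent), and a stone resting on a
  stent is in pressed contact, not point contact;
* distractors: ≤ 5 loose fragments (radius 2–4 mm, ≥ 3 mm clear of the
  tube) and a bone-like ellipsoid (8 × 6 × 25 mm half-axes), both of which
  must vanish in connected-domain filtering;
* a seeded generator with saved-and-restored RNG state: the same spec and
  seed give the identical volume on any platform, and rendering does not
  disturb the caller's RNG stream.

What the phantom does *not* emulate: CT physics (beam hardening, streak
artefacts from the metal-dense stent, dose noise correlation), anatomy
(soft-tissue background is uniform), partial encrustation of the lumen, and
real segmentation-model errors beyond simple axial dropouts. Passing the
phantom bar therefore demonstrates that the geometry and decision logic are
correct under realistic resolution and noise, not that clinical accuracy
matches any published figure; the published per-case numbers depend on a
hospital dataset and a trained network that are not reproducible here.

## Problem sizes and numerical conventions in the test suite

The suite renders 96 × 96 × 120 phantoms (≈ 1.1 M voxels, ≈ 1 s per
end-to-end case): 50 seeds per class for the class-recovery bar (≥ 90 %
required; currently all three classes recover at 100 % on the default
seeds), 50 random 20³ volumes × 3 adjacencies for labeling-oracle
equality, and 10 random cylinder orientations for re-slice rotation
invariance at the 5 % area tolerance. Coordinates are 0-based voxel indices
with the voxel centre at `origin + index · spacing`; all areas and radii are
reported in mm² and mm. Accuracies are reported to one decimal, rounded half
up — on the packaged 222-case table this yields 87.4 % (the source tables'
own counts, (54 + 140)/222, round to 87.4; published summaries have quoted
the truncated 87.3 %).

## Known limitations

* DICOM reading is deliberately minimal: uncompressed little-endian,
  axis-aligned orientation, single series. Oblique or compressed series must
  be converted to NIfTI first; the reader refuses rather than resamples.
* A stent whose segmentation breaks into pieces farther apart than the
  gap-fill limits will fail the length filter and return an indeterminate
  verdict rather than a partial analysis.
* Severity grading, lumen-internal encrustation and composition analysis are
  out of scope; the verdict is per case plus localized segments.
* The classification thresholds encode a qualitative clinical contrast; they
  are defaults to be audited against local data, not calibrated constants —
  which is why every report carries the full parameter set used.
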