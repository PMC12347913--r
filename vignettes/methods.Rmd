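---
title: "Quantifying chronic kidney damage from multi-class segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chronic kidney damage from multi-class segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephromorph)
```

## The problem

Chronic kidney damage on a PAS-stained tissue section is read along two axes:
nephron **size** (glomerular volume, cortex volume per glomerulus, tubular
cross-sectional areas — enlarged nephrons signal compensatory hypertrophy) and
**nephrosclerosis** (globally sclerosed glomeruli, interstitial expansion with
tubular atrophy, arteriolar hyalinosis, arterial intimal thickening). Visual
semi-quantitative grading of these changes is poorly reproducible; morphometry
on segmented structures is reproducible but needs every structure outlined.
Multi-class segmentation models now produce those outlines at scale, and this
package takes over from there: given a calibrated multilayer label raster (or
polygon annotation set) over a 20-class renal taxonomy, it computes the full
measure battery, validates segmentations against annotator panels, and
condenses the damage into two 0–12 ordinal chronicity scores with donor-based
reference limits.

## The taxonomy and section container

`kidney_taxonomy()` declares 20 classes in a single-parent containment tree:
Tissue splits into Cortex and Medulla; the cortex carries tubular-atrophy (TA)
clusters, the tubulointerstitium (tubules with proximal/distal subclasses plus
interstitium), the glomerular area (non-sclerosed glomeruli, globally
sclerosed glomeruli, empty Bowman capsules) and arteries-and-arterioles (with
arteriolar hyalinosis, intimal thickening, arterial lumen); the medulla
carries interlobar arteries with their own intima and lumen layers. Layers are
stored as separate masks, not mutually exclusive codes, because the classes
genuinely overlap (a TA cluster is also tubulointerstitium). A
`labeled_section` bundles the masks with a calibration (default 0.5 µm/px, the
usual 20× scan pitch; section thickness 2.5 µm, mid-range of a 2–3 µm
section), a capsule mask marking which part of the tissue boundary is
anatomical capsule, and the section kind (needle core or wedge).

Structures touching the tissue boundary *away* from the capsule were cut by
the biopsy needle, so their profiles underestimate the real structure.
`flag_edge_bisected()` marks them: a component is flagged when it comes within
`edge_eps_px` pixels (default 1) of the non-capsule tissue boundary. The
adjacency tolerance is exposed as configuration because no canonical value
exists; 1 px means "touching" at any calibration. Edge-bisected structures are
excluded from mean-area and volume computations but retained in counts and
densities — identification and use are configurable separately.

## The measures

All areas are reported in µm² (pixel count × mpp²); components use
8-connectivity by default because thin PAS-positive structures fragment under
4-connectivity.

**Glomerular volume** uses the Weibel–Gomez stereologic model on the mean
non-sclerosed glomerular profile area:
$V = (\beta/d)\,\bar A^{3/2}$, with shape coefficient $\beta = 1.38$
(spherical glomeruli) and size-distribution coefficient $d = 1.01$; both are
configurable since other choices appear in the stereology literature.

**Cortex per glomerulus** converts the areal profile density
$N_A = \text{count}/\text{cortex area}$ into a volumetric density with the
section-thickness correction $N_V = N_A/(D+T)$, where
$D = (6V/\pi)^{1/3}$ is the sphere-equivalent glomerular diameter and $T$ the
section thickness, and reports $1/N_V$. Profiles counted are non-sclerosed
plus globally sclerosed glomeruli; empty capsules are excluded (configurable).
With donor-typical inputs (2.46 NSG/mm², $V = 0.0028$ mm³, $T = 2.5$ µm) this
yields ≈ 0.07 mm³, which is why that conversion was adopted: it is consistent
with donor-scale glomerular densities without any fitted constant.

**Tubular atrophy** is summarized three ways: %TA per tubular area
($100\cdot TA/(\text{tubules}+TA)$ — the TA layer itself belongs in the
denominator because atrophic tubules are still tubular tissue), %ITA per
tubulointerstitial area ($100\cdot(TI-\text{tubules})/TI$, the
interstitium-plus-TA fraction, the surrogate for interstitial fibrosis + TA
when fibrosis cannot be told from normal interstitium), and the TA focus count
density per mm² of tubular area (same denominator as %TA).

**Arteriolar hyalinosis.** Hyaline lesions of one damaged vessel often
fragment into several detections, so lesions whose boundaries lie closer than
500 µm (about two adjacent glomerular profiles) are counted once: lesions are
linked transitively under the strict `< 500 µm` rule, and each cluster is
represented by its largest lesion, whose own area (not the cluster sum) enters
the mean AH area. Reported are the merged-lesion density per cortex mm², the
percentage of arterioles containing AH, and the mean representative area.

**Luminal stenosis.** Within "arteries and arterioles", components with
profile area > 7850 µm² (a 100 µm-diameter disc — the only printed size
criterion) are arteries; smaller components are arterioles for the AH
measures. Per qualifying artery, stenosis is
$100\cdot\text{intima}/(\text{intima}+\text{lumen})$; intima is segmented only
when thickened, so an artery without detected intima contributes 0%. The
unweighted mean over qualifying arteries is reported; cortical and medullary
(interlobar) arteries are evaluated under the same rule and reported
separately and pooled (pooled by default). Sections without a qualifying
artery report the measure as missing — common in needle cores.

Missing denominators never become silent zeros: `quantify()` returns `NA` with
a reason in `$missing`.

## Chronicity scores

Five measures are banded 0–3. %GSG and %ITA use the widely used thresholds
<10%, 10–25%, 26–50%, >50%; printed as integer ranges, they leave continuous
values in (25, 26) and just above 50 ambiguous, which we resolve as half-open
bands [0,10), [10,26), [26,50], (50,∞) — documented and overridable via
`band_spec()`. TA focus density (≤5, 6–10, 11–20, >20 per mm²), mean AH area
(≤500, 501–750, 751–1000, >1000 µm²) and cortex per glomerulus (≤0.075,
0.076–0.125, 0.126–0.175, >0.175 mm³) close each band at its upper edge. The
**nephrosclerosis chronicity score** (0–12) sums the %GSG, %ITA, TA-density
and AH-area bands; the **nephron hypertrophy and nephrosclerosis chronicity
score** replaces the %ITA band with the cortex-per-glomerulus band. A missing
component propagates (total missing) by default rather than imputing 0,
because missing denominators are real absences, not zeros; `missing_policy =
"zero"` restores the permissive behavior. `reference_report()` compares a
patient's measures against the 95th percentile (configurable — no canonical
percentile exists for such reports) of a reference cohort of at least 20
observations per measure.

## Agreement statistics

`pairwise_agreement()` computes pixel-intersection precision, sensitivity and
F1 per class, plus false-positive/negative areas as a percentage of an
evaluation region. The region defaults to the union of both sections' Tissue
masks; the denominator convention is not canonical, so `frame` and
`class_union` are offered too. Panels aggregate as the mean of per-pair
metrics over all *ordered* annotator pairs — ordered, because precision and
sensitivity swap when test and reference swap, and averaging both directions
makes that symmetry explicit (pooled-area aggregation is available).

## The synthetic section generator

No patient images ship with the package, so validation runs on synthetic
sections with known ground truth. `generate_section()` lays out a needle core
(capsule band at one end, needle-cut long edges) or wedge (capsule along the
top) as analytic vector shapes — discs for glomeruli, tubules and AH lesions,
ellipses for TA foci, annuli for artery walls, intima and lumen — then
rasterizes them. True areas are therefore known *before* rasterization, which
keeps the oracle separate from the raster pipeline being tested. Placement is
non-overlapping with a 3-px minimum gap (so rasterized components never touch
and counts are exact), honours the taxonomy nesting, and fails loudly with a
packing error when the requested structures cannot fit. Proximal and distal
tubules differ only in their size parameters: every downstream measure is
geometric, so no texture is simulated.

Defaults are donor-like at the native 0.5 µm/px: cortex 6.7 mm², 2.46
non-sclerosed and 0.09 sclerosed glomeruli per mm², glomerular profile areas
lognormal with mean ≈ 16,000 µm² (the profile area consistent with a 0.0028
mm³ Weibel–Gomez volume), proximal/distal tubule means 2768/1523 µm², AH
lesions near 138 µm². `tumor_scene_spec()` switches to wedge geometry with the
tumor-cohort composition (≈2.5 glomeruli and TA foci per mm², 10% GSG,
tubule means 4205/2598 µm², AH ≈ 405 µm², stenosis ≈ 28%); since a full 135
mm² wedge is far beyond what a workstation test needs, its default cortex area
is scaled down with all densities preserved. Within-section lesion-size
spreads are not reported anywhere, so the generator uses moderate lognormal
spreads (e.g. SD 60 µm² for donor AH lesions) chosen once as
histologically plausible.

What the generator does **not** emulate: staining texture and scanner
variability; tubule crowding beyond circle packing (random sequential disc
packing saturates near 50% of the tubulointerstitium, so synthetic %ITA sits
around 45–60%, the upper end of the donor distribution rather than its 36.5%
mean); irregular glomerular and capsular outlines; and true wedge-scale
sections. Passing recovery tests therefore demonstrate that the measure
pipeline is exact on calibrated rasters of known content — not that any
segmentation model is accurate on real tissue.

`perturb_annotation()` degrades a section into a simulated second annotator
(per-class boundary dilation/erosion, whole-component class flips) for
exercising the agreement module; a zero-magnitude perturbation returns the
identical section.

## Numerical and testing choices

Rasterization fills a pixel when its centre lies inside the analytic shape,
so a disc of radius $r$ px has relative area error with SD well under 1% for
the structure sizes generated here; the validation suites demand exact count
recovery and ≤ 2% relative error on all area and ratio measures across 25
seeded donor-like and tumor-like scenes. Those suites run scenes of 0.5–1.8
mm² of cortex — large enough that every structure family appears, small
enough that the whole suite stays within a few minutes on one CPU. Raster ↔
polygon conversion traces component boundaries along pixel-cell edges
(corners at half-integer pixel coordinates) and rasterizes polygons under the
even-odd rule evaluated at pixel centres, which makes
rasterize∘vectorize∘rasterize exactly idempotent; pixel centres falling
exactly on a user polygon's edge follow a documented half-open convention.
Component extraction labels 4-connected runs and merges diagonal neighbours
with a union–find pass; equivalence against a naive flood-fill oracle is part
of the test suite. Lesion distances are measured between boundary-pixel
centres, within half a pixel of the geometric gap at any calibration.

## Known limitations

- Interstitial fibrosis is not distinguished from normal interstitium — by
  design, %ITA is the reported surrogate.
- Segmental sclerosis and periglomerular fibrosis have no dedicated classes;
  glomerular handling treats tufts as whole profiles.
- The CLI reads single-resolution label rasters or GeoJSON; pyramidal
  whole-slide formats and model inference are out of scope.
- Reference limits are plain percentiles; no age- or sex-specific modelling.
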