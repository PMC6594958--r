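---
title: "nestkin: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nestkin: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestkin)
```

`nestkin` quantifies the establishment of the spermatogonial stem-cell
(SSC) pool from three kinds of measurement: 3D confocal volumes of whole
neonatal testes, flow-cytometry event tables, and single-cell RNA-seq
count matrices. This vignette explains the models behind each stage, the
tunable parameters and their defaults, what the synthetic-data generators
emulate, and the places where the design was genuinely open and a choice
had to be made.

## 1. Nest detection and statistics

### Model

Germ cells expressing the ID4-eGFP reporter are rendered by the
microscope as roughly spherical bodies of ~20 µm diameter, sectioned at
5 µm in z. Detection is thresholding (Otsu on the nonzero voxels by
default, a fixed value otherwise) followed by 3D connected-component
labelling at 26-connectivity and a minimum-volume filter. Each object is
measured in physical units: unweighted centroid of voxel centres, volume
= voxel count × voxel volume, mean intensity.

A *nest* is a group of ≥ 3 germ cells pairwise chained at ≤ 10 µm
separation. Operationally this is single-linkage hierarchical clustering
of an inter-object distance matrix cut at 10 µm — equivalently, connected
components of the ≤ 10 µm adjacency graph (the test suite checks this
equivalence against a brute-force union-find oracle on every run). Ties
at exactly the cutoff are merged ("no more than 10 µm"), with a 1e-9
relative epsilon absorbing floating-point noise.

### Distances: three modes

With ~20 µm cells, a 10 µm separation can only be surface-to-surface, so
centre-to-centre distances are geometrically unable to express the
criterion for non-overlapping cells. Three modes are provided:

* `center` — Euclidean centroid distance;
* `border` — centroid distance minus the equivalent-sphere radii derived
  from the two object volumes, floored at 0;
* `voxel_border` (default in `nest_pipeline()`) — the exact minimum
  distance between the two objects' surface voxels, computed from the
  segmentation label map.

The equivalent-sphere border mode is exact for single spherical cells but
systematically *overestimates* gaps to merged multi-cell objects: a
two-cell "dumbbell" 40 µm long has an equivalent-sphere radius of only
~13 µm, so a third cell touching its far end appears > 10 µm away and the
nest splits. Because touching cells merge routinely at a 5 µm z-step, the
voxel-accurate mode is the default whenever a label map is available; it
is what a 3D-ROI border-to-border measurement reports. The
equivalent-sphere and centre modes are retained both for objects without
a label map and because which convention the original ImageJ workflow
used is not documented; the default is a declared choice, not a claim
about the original.

### Cell counting and nest statistics

Touching same-class cells are not split at detection; instead an object's
cell content is estimated as its volume over the reference single-cell
sphere volume (diameter 20 µm → 4189 µm³). The per-object integer
estimate is `round(volume / reference)`, clamped to ≥ 1. For the ≥ 3-cell
nest rule, however, `nest_pipeline()` passes *fractional* volume
equivalents into the grouping and rounds once at the group level:
rounding per object first and summing afterwards accumulates error (two
objects of 1.4 cell-equivalents each would count 1 + 1 = 2 instead of
round(2.8) = 3), and group-level rounding removes exactly this artefact.

Nest class is assigned from the nest's (cell-count-weighted) mean eGFP
intensity — not a majority vote over member objects — because the average
intensity within a nest is the quantity that defines its classification.
Per class, the summary reports the percentage of cells in nests
(denominator: *all* detected cells of the class, nested or not — whether
sub-threshold pairs belonged in the original denominators is not
documented, so the inclusive convention is used and stated), the average
nest size in estimated cells, and the total nest count.

When imaging covers only part of an organ (the older P5–P9 testes),
`scale_total_nests()` multiplies the observed count by the ratio of total
cells of that subtype (from flow cytometry) to cells captured by imaging.
The estimator is exactly the identity under full imaging and is
consistent under partial imaging up to slab-boundary effects: nests cut
by the imaged boundary can drop below three visible cells (losing a nest
but keeping its visible cells in the denominator), which biases the
estimate a few percent downward when the organ is only a few nest-extents
thick. In the real organ — millimetres thick versus a ~40 µm nest — the
effect is negligible; the synthetic evaluation uses a volume thick
relative to nest extent for the same reason.

### Autofluorescence exclusion

Interstitial (Leydig-cell) autofluorescence produces eGFP-channel objects
with no tdTomato lineage label. When a tdTomato volume is supplied,
objects whose object-mean tdTomato intensity is below a threshold
(default 0.1 on the normalised scale) are discarded. The mean over the
object's own voxels is used rather than the intensity at the centroid
voxel: a merged two-cell object's centroid falls in the gap between the
cells, where neither channel has signal.

### Detection parameters

The original ImageJ settings (threshold, minimum object size) are not
documented, so `detection_config()` declares its own defaults: Otsu
thresholding, minimum object volume 250 µm³ (about 6 % of a reference
cell — large enough to drop noise specks, small enough to keep genuinely
small cells), 26-connectivity (merges diagonal contacts, which matters at
a coarse z-step).

## 2. The volume generator

`simulate_testis_volume()` renders germ cells as solid spheres of
class-specific eGFP intensity (log-normal around 0.80 for Bright, 0.40
for Mid on the normalised scale) and a shared tdTomato level, placed
inside straight cylindrical "tubules" (default 8 tracks of 35 µm radius —
a testis is densely packed with seminiferous cords, and a sparse track
count would leave large empty regions that distort depth-fraction
experiments). Nests are built by chaining cells at surface gaps sampled
inside (0.25, 0.85) × `intra_nest_gap_um` (default 6 µm); cells of
different nests and singletons are kept > `inter_nest_min_gap_um`
(default 35 µm) apart. The construction validates
`intra < cutoff < inter` ("well-separated"), so planted nest membership
is unambiguous under the 10 µm rule.

Two further validity constraints make the planted configurations
*recoverable*, not merely well-separated:

* cells within a group are strictly disjoint (≥ 0.5 µm surface gap):
  overlapping spheres would lose their intersection volume and the
  volume→count conversion would systematically undercount;
* each group's diameters (drawn i.i.d. N(20, 2) µm) are resampled until
  the summed relative volume rounds back to the group's cell count within
  ±0.3 cells. Without this, a 3-cell nest of 17 µm cells genuinely
  contains only ~2.2 reference-cell volumes, and *no* volume-based
  analysis could call it a nest of three — the ground truth itself would
  be inconsistent with the measurement model.

Rendering samples each sphere at the anisotropic voxel grid (default
1 × 1 × 5 µm), adds Gaussian background noise (σ = 0.02), clamps to
[0, 1] and quantises to 16 bits, which makes TIFF round trips exact.
Placement is rejection sampling with an explicit retry budget (default
10,000 draws) and a named error on failure. There is no PSF, bleaching or
depth attenuation: nest calling depends on centroids and volumes, not
texture, so optics simulation would add cost without exercising any
additional code path. Autofluorescent blobs (eGFP-only, 5–8 µm radius)
are placed outside all tubules with a 5 µm clearance so they segment as
their own objects.

## 3. Cytometry gating and kinetics

*Germ gate.* The tdTomato threshold is the 99.5th percentile of an
unstained control of the same age; by construction ~0.5 % of true
negatives pass. *Tertiles.* For each sample, the eGFP⁺ range — positivity
threshold to sample maximum — is split into three equal-width bins on the
log10 scale (cytometry intensities span decades; whether the original
thirds were linear or log is not stated, so both are offered with log as
the default). Bins are closed on the left of the upper bin, so an event
exactly at a cutpoint takes the higher class. Boundaries are per-sample,
not pooled, because each sample's signal is divided into thirds
independently.

*Cell cycle.* The 2N mode is located as the peak of a 128-bin histogram
and the gate sits at 1.5 × mode (3N). S-phase is modelled (and generated)
as a uniform DNA-content bridge between the 2N and 4N peaks, so half of S
falls below a 3N gate; the S/G2/M estimate therefore adds twice the mass
observed in (1.25 × mode, 1.5 × mode], which is exactly unbiased under
the uniform-bridge model, adds nothing when the bridge is empty, and
ignores the 2N peak (a 5 % CV Gaussian has essentially no mass beyond
1.25 × mode). The raw above-gate fraction is also returned.

*Kinetics.* Fold change at age *i* is count(*i*)/count(*i−1*). A plateau
is flagged at the first age opening `plateau_run` (default 2) consecutive
intervals with |fold − 1| ≤ `plateau_tol` (default 0.15); the plateau
definition is artefact-defined since the source material describes
plateaus qualitatively. The events→cells-per-animal factor is
user-supplied metadata (default 19.2 in the flow generator, sized so the
Bright plateau sits near 25,000 cells per animal).

The flow generator's default per-age subset counts encode the
developmental story the pipeline is meant to measure: a 4.21-fold Bright
burst between the third and fourth postnatal days followed by a plateau,
Mid and Dim expanding later, quiescence (S/G2/M ≈ 0.05) before mitotic
reactivation and ~0.45 afterwards, and a KIT⁺ compartment of ~13 % of the
germline that is ~94 % Dim/eGFP⁻. Subset eGFP bands sit strictly inside
the log-thirds of the positive decade range, so band-separated subsets
are recovered with zero misclassification — by design, the recovery test
checks the gate arithmetic, not the generator's difficulty.

## 4. Single-cell annotation

*QC.* Thresholds are per library and strict (`>` / `<`): a cell at
exactly the boundary fails, matching printed threshold conventions. The
default mitochondrial cap is 25 % for all libraries. *Germ selection*
keeps cells with ≥ 1 summed *Dazl* + *Ddx4* count. *Normalisation* is
counts / cell-total × 10⁴, log1p. *Variable genes*: per-gene dispersion
(variance/mean of normalised expression) is z-scored within 20
equal-frequency bins of mean expression; genes with z > 1 are kept.

*Clustering* is PCA (default 20 PCs — the original jackstraw-selected
"31 significant PCs" is a data-specific outcome replaced by a fixed,
configurable count) → KNN graph (k = 20, Euclidean distance in PC space)
→ Louvain modularity at a given resolution, with a fixed seed and labels
relabelled by decreasing size. The bespoke logic is the *resolution
criterion*: scan a grid (default 0.2–1.2) and choose the smallest
resolution at which the reference population (e.g. the known ~10 % SSC
pool) is enriched within a single cluster — containment ≥ 0.8 and purity
≥ 0.5 by default. The full per-resolution table is always returned, and
an error carrying it is raised when no grid value qualifies.

*Markers and identity.* Dot-plot statistics are cluster-mean
log-normalised expression z-scored **across clusters** (the dot-plot
convention; per-gene cluster values sum to zero) and detection fraction
(share of the cluster's cells with a nonzero count). A gene passes the
marker criterion when some cluster has scaled expression > 0 and
detection > 10 %. Cluster identity scores are panel means of scaled
expression; the SSC-like label goes to the cluster maximising SSC-score
minus differentiation-score, with the full table exposed and no hidden
thresholds.

*Replicate agreement* uses the modified multivariate RV coefficient:
column-centre both matrices, form the row-space inner-product matrices,
zero their diagonals (the self-similarity terms that inflate the plain RV
for high-dimensional data), and take the Frobenius cosine. The replicate
unit is pseudobulk — per-gene mean log-normalised expression per library
— because the original feature space for replicate correlations is not
specified; pseudobulk is the stable, interpretable choice.

*Covariate regression during scaling* (the "vars.to.regress" step of the
original workflow) is deliberately omitted: it is third-party behaviour
whose effect on synthetic data with no batch structure is nil; the
divergence is documented here.

## 5. The count-matrix generator

Cells carry a latent continuum coordinate *u* ∈ [0, 1] (Beta-distributed
per age, shifting from low to high across development). Log2 expected
expression is a per-gene baseline plus slope × (*u* − ½): −2 for the
SSC program, +2 for the differentiation program (anti-correlated
programs), −3 for the pluripotency panel, 0 elsewhere. A rare population
(exactly `round(0.10 × n)` cells, seeded sample) sits at low *u* with a
20-gene marker panel boosted by 3 log2-fold by default — a population of
this kind is set apart by a broad transcriptional program, so a
handful-of-genes default would understate its signature. Counts are
negative binomial (size 2) around library-size-scaled means with 10 %
extra dropout; mitochondrial genes are scaled to hit a per-cell target
fraction (normal cells ~5 %, clamped ≤ 20 %; optional low-quality cells
~55 %, clamped ≥ 45 % — the clamps keep the two populations separable
around the 25 % QC rule after count-level noise). Gene-level baselines
are drawn under a *separate* seed (`gene_param_seed`) so replicate
simulations with different seeds share the same biology — as real
replicate libraries do — which is what makes replicate RV values of
~0.99 meaningful rather than accidental.

## 6. Numerical choices and degenerate inputs

* Single-linkage cut height: `cutoff × (1 + 1e-9)` to include ties.
* All-zero volumes segment to an empty table (not an error); zero cells
  of a class yield an undefined-flagged summary row, never NaN.
* Zero-variance genes z-score to all-zero rows and are flagged;
  single-cluster marker statistics return zero scaled expression.
* Quantile ties in variable-gene binning collapse to fewer bins; a fully
  degenerate mean distribution falls back to one bin.
* The modified RV of a constant matrix is NA with a warning.
* Determinism: all generators take an explicit seed and are bit-exact
  under `config + seed`; clustering seeds the community search; the
  pipeline stamps every output table with an MD5 hash of its
  configuration, and identical configurations reproduce byte-identical
  tables.

## 7. Problem sizes used in the checks

The test suite and acceptance script exercise: 100 random point
configurations of up to 500 objects against the brute-force nest oracle;
20 noisy 400 × 400 × 200 µm volumes with 8 + 3 planted nests (exact
recovery, pooled percent-nested within 2 points); 20 half-depth
300 × 300 × 300 µm volumes for the scaling estimator (mean within 10 %);
10,000-event DNA-content recovery at S/G2/M ∈ {0, 0.3, 0.5} (± 0.03);
50 random QC matrices against brute-force re-evaluation; and 10 seeded
1000-cell × 500-gene matrices with a planted 10 % population at 2
log2-fold for the resolution criterion (containment ≥ 0.8). These sizes
were chosen to make each property measurable with comfortable
statistical margin while keeping a full run in minutes on one CPU.

## 8. Known limitations

* The generators emulate structure, not raw physics: no optics (PSF,
  bleaching, depth attenuation), no spectral spillover or compensation in
  cytometry (FCS parsing is out of scope; tables come in as CSV), no
  read-level sequencing simulation, no doublets beyond the printed
  threshold rules.
* Real nest spatial statistics (inter-nest spacing distributions) are not
  reported anywhere authoritative; the generator's spacing defaults are
  free parameters of the artefact, not calibrated estimates.
* Whether the original distances were centre- or border-based, and the
  original ImageJ threshold settings, are undocumented; defaults here are
  declared choices, and both distance conventions (plus the
  voxel-accurate mode) are exposed.
* The scaling estimator inherits a small negative bias when the imaged
  slab is thin relative to nest extent; this is a property of the
  estimator itself, quantified in the tests, not an implementation error.
* Passing the synthetic recovery tests demonstrates the correctness of
  the quantification machinery under the stated models; it does not, by
  itself, validate biological conclusions about real testes.
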