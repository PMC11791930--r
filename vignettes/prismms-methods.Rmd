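---
title: "Mass-guided two-pass single-cell MSI: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-guided two-pass single-cell MSI: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(prismms)
```

This vignette is the package's own account of the science it implements:
the two-pass acquisition model, the single-cell extraction chain, the Monte
Carlo consensus-clustering decision rule, the effect-size statistics, and —
because every one of these stages is exercised against simulated ground
truth — what the synthetic generator does and does not emulate.

## The two-pass acquisition model

Single-cell MSI of low-mass metabolites is constrained by speed: hydrophilic
compounds below ~200 Da degrade while a slide sits at room temperature, so
any optical pre-imaging step costs signal. The workflow modelled here
replaces optical guidance with a mass-guided pass: a coarse *PreScan*
(default 200 µm raster) is acquired quickly over the whole sample, an ion
image of a ubiquitous cell marker (default FA 18:1 [M−H]⁻, *m/z* 281.2485)
is thresholded, and only the cell-containing regions are re-acquired as a
fine *DeepScan* (default 20 µm raster).

**Threshold.** For a marker ion image with cell intensities $I$,
$\kappa = \bar I + \alpha\,\sigma$, computed over *all* grid cells of the
image, empty pixels included. Two conventions had to be fixed because they
change $\kappa$ at the margins:

* $\sigma$ is the *population* standard deviation (divide by $n$). The same
  convention is used for z-scaling below, so a threshold in "standardized
  units" means the same thing at both stages.
* Binarization is strict ($I > \kappa$): an all-zero image yields an empty
  mask, and ties at $\kappa$ — practically impossible in float data — are
  excluded deterministically.

$\alpha$ (default 1, integer or real) is the single sensitivity dial; raising
it shrinks the mask monotonically (a property the test suite asserts).

**Mask to regions.** The binary mask is resized to the DeepScan raster by
integer block replication (200 µm → 20 µm is factor 10; non-integer raster
ratios are refused rather than resampled), optionally dilated with a square
structuring element of side $2(d-1)+1$ — the default $d = 1$ means no
change; some protocols call this parameter a "dilution factor", it is the
same thing — and decomposed into 8-connected components. Eight-connectivity
is used because a cell body sampled at a coarse raster should not be split
by a diagonal adjacency; the same convention is reused for cell clustering.
Each component becomes one measurement region whose polygon is the outer
boundary of its pixel squares, holes filled (a measurement region is a
solid area). At diagonally-touching pixels such a boundary cannot be a
strictly simple polygon: the tracer resolves the ambiguity with a
right-most-turn rule, so edges never cross but the contour pinches (repeats
a vertex) at the shared corner. Region polygons are emitted
counter-clockwise in stage micrometres, with sequential names
(`ROI_001`, ...) — region naming is not prescribed by any acquisition
convention, so the package picks a deterministic one.

**Region documents.** Vendor region files are proprietary, so the package
defines a minimal documented XML dialect (`prismms-mis-1`; see
`inst/extdata/example.mis`): root `ImagingDocument` with `MethodName`,
`Raster` (µm), an optional affine `Transform` (grid vertex → stage µm,
row-wise `a11 a12 a21 a22 tx ty`) and one `Area` per region holding
`Point` vertices `x,y` in µm. Adapting real vendor files means writing one
translator to and from this dialect; everything the DeepScan hand-off needs
is carried.

**imzML.** Imaging data move through standard imzML 1.1 + ibd file pairs
(continuous or processed mode, uncompressed 32/64-bit floats stored
externally, UUID linkage, MD5 checksum). Intensities default to 32-bit on
disk and full precision in memory. The writer derives the UUID from the
dataset content, so identical data written twice produce byte-identical
files — the property that makes seeded synthetic fixtures reproducible.
Grid coordinates are 0-based internally (x = column, y = row, origin
top-left) and 1-based on disk per the imzML convention. Two tolerance
semantics coexist and are never converted silently: read-time peak
alignment uses ppm (default 10 ppm), annotation-based peak reduction uses
absolute Dalton (default ± 0.005 Da around annotations with FDR ≤ 10 %).

## From pixels to cells

DeepScan spectra are assembled into a pixel-by-feature matrix
$\mathbf M$ on a common axis (greedy single-linkage grouping of sorted
peak masses at the ppm tolerance). The chain is fixed as:

1. **Normalize.** $\mathbf M'_{ij} = \mathbf M_{ij} / \mathbf M_{i,IS}$
   against the internal standard spiked into the matrix (Trp-d5, [M−H]⁻
   *m/z* 208.1140), which cancels per-pixel multiplicative gain from laser
   and matrix variation. Rows without IS signal have no valid
   normalization: they are dropped with a logged count, never zero-filled,
   and the drop happens *before* standardization so they cannot distort
   column moments. Vesicle data, which carry no spiked standard, use total
   ion current normalization instead (row / row sum).
2. **Standardize.** Per-column z-scaling to $\mu_j = 0,\ \sigma_j = 1$
   (population sd). Constant columns cannot be scaled; they map to zero
   and are flagged.
3. **Select.** Pixels with standardized marker intensity ≤ 3 are removed
   (strictly greater than 3 survives). For two-population vesicle fields
   the per-lipid selections are united, since the two compositions share
   no peak.
4. **Cluster.** Remaining pixels form 8-connected components. Components
   of ≤ 7 pixels are single cells; larger ones are aggregates, kept in the
   output for audit but excluded from statistics. The 7- and 20-pixel
   bounds are both exposed (`max_single_cell_pixels`,
   `max_cluster_pixels`); since any component above 7 pixels is excluded
   either way, the 20-pixel bound is a documented hard ceiling rather than
   an extra filter.
5. **Average.** Each cell's mean spectrum over its member pixels becomes a
   row of the cell-level matrix.
6. **Re-standardize.** The cell-level matrix is z-scaled again before any
   between-group statistic, so the unit-variance assumption of the
   effect-size formula holds at the level where the comparison is made.
   Whether to re-standardize at cell level was genuinely open; the package
   does, and keeps both matrices.

## Monte Carlo reference-based consensus clustering

For a candidate cluster number $k$, `consensus_cluster()` repeatedly draws
a fraction (default 0.8, standard consensus-clustering practice) of the
objects without replacement, clusters the subsample hierarchically
(Euclidean distance, complete linkage by default, configurable) and cuts at
$k$; the consensus entry $(i,j)$ is the fraction of co-clusterings among
iterations where both objects were sampled. Stability is summarised by the
PAC score: the fraction of off-diagonal consensus entries strictly inside
the ambiguity window (default $(0.1, 0.9)$) — 0 for perfectly stable
clusterings.

The null model is the key step: `simulate_reference()` draws same-shape
datasets from a multivariate normal with the data's mean vector and
covariance, sampled in principal-component space (univariate: a normal with
the sample mean and sd) — data with the observed scale but *no*
subpopulation structure. A column-permutation null is available behind
`ref_method = "permute"`. Each reference dataset is consensus-clustered
with the same number of resampling iterations as the real data (the inner
iteration count for references is not separately specified anywhere, so
symmetry is the least surprising choice). Per $k$:

$$\mathrm{RCSI}_k = \ln\frac{\overline{\mathrm{PAC}}^{\,\mathrm{ref}}_k}
{\mathrm{PAC}^{\,\mathrm{real}}_k},\qquad
p_k = \frac{1 + \#\{\mathrm{PAC}^{\mathrm{ref}}_k \le
\mathrm{PAC}^{\mathrm{real}}_k\}}{N_{\mathrm{ref}} + 1}.$$

PAC values are floored at `pac_eps` ($10^{-4}$) inside the ratio so RCSI is
always finite. The add-one correction keeps $p > 0$; consequently
$p < 0.01$ is attainable only with at least 100 reference iterations, which
is why the defaults run 200 real and 200 reference iterations per $k$ up to
maxK = 8 under the fixed analysis seed 42. The selected $k$ is the one
with the highest RCSI among candidates with $p < 0.01$; if none qualifies
the feature is declared homogeneous — the branch that lets a
non-responding cell line report "no subpopulations" rather than a forced
split.

Determinism and order: all randomness runs under a private seed (the
caller's RNG state is untouched), and objects are canonically ordered
internally before any draw, so the selection is invariant to input row
order. Final assignments at the selected $k$ come from hierarchically
clustering the consensus dissimilarity $1 - C$.

A `repeats` argument reruns the whole procedure and reports the majority
selection. One reading of the procedure's description is five such outer
repeats; since a single run already aggregates hundreds of resamples and
the cost is linear in repeats, the package defaults to `repeats = 1` and
leaves the majority-vote mode available.

**Linkage.** Complete linkage is the default. It is worth knowing its
failure mode, which the test suite's development exposed: at small $n$
(tens of objects) the $k=2$ cut occasionally isolates an extreme point
instead of the two modes, inflating the real PAC; conversely
average-linkage nulls can produce spuriously stable singleton splits
(reference PAC near 0) that weaken the empirical p-value. At the sample
sizes the workflow targets (hundreds of cells) complete linkage separates
planted structure from its reference distribution with a wide margin; for
very small populations, treat a non-significant result with the same
caution as any underpowered test.

**Labels.** For binary marker axes (k = 2 or homogeneous per marker), the
cluster with the higher mean marker intensity is the "+" side; homogeneous
markers label all cells "−"; the per-cell label is the cross-product
(e.g. `ita+taur-`), and cells negative on every axis are flagged for
omission from population fractions. Markers selecting k > 2 are refused for
labelling rather than coerced.

## Effect-size statistics

Cohen's D per feature is $(\mu_1 - \mu_2)/\sigma_{12}$ with $\sigma_{12} = 1$
on standardized data (the pooled-sd denominator is available via
`assume_unit_sd = FALSE`). The sign convention — group 1 minus group 2,
treatment first — is stated in the output so activation markers come out
positive. Raw p-values come from Welch's two-sample t-test by default; the
underlying test is not dictated by the formula, and Welch is robust to the
unequal variances typical of activation data (Mann–Whitney is available via
`test = "wilcoxon"`). Benjamini–Hochberg adjustment (`stats::p.adjust`)
controls the FDR across features; a feature is `up`/`down` when |D| > 0.2
*and* adjusted p < 0.05 (both thresholds configurable; tissue-level
comparisons conventionally tighten p to 0.01). Features constant in both
groups are untestable: p is set to 1 and the row flagged.

Adjacent tissue pixels are statistically dependent, which inflates
significance if treated as independent samples. `subsample_pixels()`
therefore draws 1000 random pixels per condition, repeats 10 times, and
averages both D and the p-values (raw and adjusted are averaged
separately; classification applies the thresholds to the averaged adjusted
p — averaging before or after adjustment was open, and both averages are
reported). `marker_concordance()` compares classification directions
across volcano tables from different model systems.

## The synthetic ground truth

`generate_field()` emulates the workflow's validation object: a field of
cell-sized spheres of known composition (two single-lipid vesicle classes,
diameters uniform 5–50 µm) scattered without overlap (rejection sampling,
bounded retries) on a slide scanned at 200 µm and 20 µm. Rasterization
rule: a DeepScan pixel belongs to an object iff the pixel centre lies
inside the disc; a pixel reachable from two near-touching objects goes to
the nearer centre — mirroring how unresolved adjacent objects produce
apparent double-positives in real data. Per covered pixel, each signature
feature draws a log-normal intensity (MSI intensities are positive and
right-skewed; default $\sigma_{\log} = 0.3$); background matrix peaks
(default: the 1,5-DAN matrix ion at *m/z* 157.0771) and an
internal-standard channel are present in every pixel. PreScan pixels are
the sums of their 10 × 10 DeepScan children times multiplicative
acquisition noise (default $\sigma_{\log} = 0.1$; with noise off the sum is
exact, a conservation law the tests assert). Everything is deterministic
given the seed, down to byte-identical imzML files.

`generate_activation_experiment()` skips the imaging layer and draws
cell-level standardized values directly: a fraction of cells is
"activated", with an up-marker shifted by $+e$ and a down-marker by $-e$
standardized units (defaults emulate the itaconate-up/taurine-down marker
pair) over otherwise null features.

What the generator does *not* emulate — and hence what green tests do not
show about real data: ionization suppression and matrix effects, isotope
envelopes, peak-shape/centroiding artefacts, spatial intensity gradients,
chemical noise correlated across features, and optical co-registration
error. It validates the *pipeline logic* (thresholding, geometry,
normalization algebra, clustering decisions, statistics), not instrument
physics.

## Numerical choices and degenerate inputs

* Population sd throughout (threshold and z-scaling); documented because it
  shifts z-thresholds at small n relative to the sample-sd convention.
* Strict inequalities at both thresholds (κ and z ≤ 3 removal).
* Consensus pairs never co-sampled (possible only at very low iteration
  counts) are set to 0 with a logged count; consensus diagonals are 1.
* Ties in the RCSI argmax resolve to the smallest k (`which.max`).
* `pac_eps = 1e-4` floors PAC ratios; reference covariance estimation falls
  back to a diagonal covariance with a logged warning when singular.
* Empty masks, empty region lists, all-negative truth masks, constant
  features, single-row matrices, rows without IS signal, and annotation
  tables that empty under the FDR filter all have explicit refusal or
  flagging behaviour rather than silent propagation — the tests pin each.

## Problem sizes used by the checks

The packaged checks are sized for a desk-scale single-CPU run: the
end-to-end field uses 300 objects on a 4 × 4 mm field (M3C at maxK = 4,
100/100 iterations per feature); the cluster-number recovery check uses
n = 200 with maxK = 8 and 100/100 iterations; the mixture-fraction check
uses n = 500 cells (maxK = 3, 60/100); the type-I property for M3C runs 25
seeded repetitions with an a-priori allowance of 3 false positives, and
the volcano type-I check pools 100 seeded repetitions of 50 null features.
These sizes are the package's own choices for routine verification; all
are parameters, and nothing prevents running the same code at instrument
scale.

## Known limitations

* The imzML reader targets well-formed files written by this package,
  pyimzML-style writers or converters that tag arrays via
  referenceable param groups; exotic mzML variants (compressed arrays,
  inline base64 payloads) are not supported.
* The `.mis` dialect is deliberately minimal; vendor round-tripping needs a
  translator.
* Consensus clustering cost grows as (real + reference) iterations ×
  candidate k × hclust(n²); per-pixel clustering of whole images is out of
  scope by design — the workflow clusters cells, not pixels.
* Formula parsing covers Hill-notation strings with D/¹³C/¹⁵N labels; no
  nested groups, no multiply-charged adducts, no isotope-pattern
  simulation.
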