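---
title: "Quantifying the geometric precision of replicate virtual bone models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the geometric precision of replicate virtual bone models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

A virtual bone model is a triangle mesh extracted from a segmented CT
image. When the same bone is scanned and segmented several times, the
resulting meshes differ: image noise, slice thickness, exposure, scanner
and operator thresholding all perturb the reconstructed surface. Any
measurement taken *on* the model (an osteometric distance, an implant fit,
a fracture reduction target) inherits this variability, so the practical
question is not whether replicate models differ but *by how much, where on
the surface, and whether the spread stays under clinically acceptable
error*. `meshprecision` implements the replicate-scan precision analysis
for this question and a synthetic generator so the whole pipeline can be
exercised end to end without patient data.

## The core statistic: balanced single-point SD

Given a replicate set of $n$ meshes of the same object, pick one replicate
as reference. For each reference vertex, `nn_distances()` finds the
distance to the nearest vertex of each other replicate, giving $m = n - 1$
deviations per vertex. `single_point_sd()` pools them into a per-vertex
spread estimate. The default `"rms"` estimator treats the deviations as
centred on the reference point itself,

$$\mathrm{sd}(v) = \sqrt{\tfrac{1}{m}\sum_{i=1}^{m} d_i(v)^2},$$

rather than on their own mean. The alternative `"sample_sd"` (the standard
deviation of the $d_i$ about their mean) is also provided, but it vanishes
whenever all deviations happen to share the same magnitude — a systematic
offset of the reference would read as zero spread — so `"rms"` is the
default reading of per-point variability.

Because the choice of reference is arbitrary, `balanced_sd()` repeats the
computation with every replicate in turn acting as reference, transfers
each field onto the first replicate by nearest-vertex lookup, and averages
the $n$ fields per vertex. This removes reference-choice bias; the result
is a `point_sd_field` attached to replicate 1.

Two caveats are inherent to the estimator and documented rather than
hidden:

* **Nearest-neighbour underestimation.** The nearest vertex of another
  replicate can only be at most as far as the true displaced counterpart,
  so the per-vertex SD is a lower bound on the true surface displacement
  spread. The effect is small while vertex spacing is much larger than the
  displacements (see the parameter-recovery discussion below) and grows as
  the two scales approach each other.
* **Correlated deviations.** Each nearest-neighbour distance mixes the
  reference point's own offset with the other replicate's, so the $m$
  deviations at one vertex share the reference offset and are not
  independent. The balanced average over references mitigates, but does
  not remove, this correlation.

## Thresholds and the $2\sqrt{2}$ propagation law

A distance measured between two model points combines two per-point
errors. If both points vary independently with the same per-point SD, the
difference of two such measurements has SD $\sqrt{2}\,\mathrm{sd}$, and a
2-SD ("95 %") interval on the measured distance spans

$$\mathrm{CI}_{95} = 2\sqrt{2}\,\mathrm{sd}.$$

`sd_to_ci95()` and `ci95_to_sd()` implement this law exactly. Reading it
backwards converts acceptable measurement errors into per-point SD
ceilings: the classical 2 mm acceptable osteometric error maps to
`ci95_to_sd(2) = 0.707` mm, usually quoted as 0.7 mm, and CIs of 1 mm and
0.5 mm map to 0.354 mm and 0.177 mm, quoted as 0.35 mm and 0.175 mm. The
package's default threshold set `sd_thresholds()` is
`c(0.07, 0.175, 0.35, 0.7)` mm. Note one deliberate inconsistency carried
over from the conventional table: under the same law the 0.07 mm cutoff
corresponds to a 0.198 mm CI, yet it is habitually labelled "0.25 mm";
we keep the conventional cutoff values and document the mismatch instead
of silently "fixing" either number.

`fraction_table()` reports, per condition, the fraction of vertices with
SD strictly below each threshold (plus strictly above the largest), and
`colour_map()` paints the reference mesh by threshold band for export as a
colour PLY.

## Comparing conditions: two-sample Kolmogorov–Smirnov

Two conditions are compared by pooling each condition's per-vertex
balanced SD values and computing the two-sample KS statistic
$D = \sup_x |F_a(x) - F_b(x)|$ over the exact pooled support
(`ks_compare()`). Alongside $D$ the package reports `sd_at_max`, the SD
value at which the largest ECDF gap occurs (the smallest such value on
ties), which localises *where* in the spread distribution two conditions
diverge. The p-value uses the asymptotic Kolmogorov distribution,
evaluated by an alternating series for moderate-to-large arguments and by
the theta-function representation for small arguments. With $10^4$–$10^5$
spatially correlated vertices treated as independent samples this p-value
is anti-conservative and should be read qualitatively; $D$ itself is the
interpretable effect size.

## The synthetic generator

The generator provides two paths whose defaults are study conditions, not
tuning knobs.

**Fast path (mesh perturbation).** `make_base_shape()` builds closed
phantoms (icosphere, ellipsoid, capsule, and a three-lobed
"pelvis_phantom" with ridges and narrow gaps, meshed from an implicit
field). `perturb_replicates()` displaces every vertex along its outward
normal by $N(0, \sigma(x)^2)$, with optional spherical patches of elevated
$\sigma$ and optional random edge-collapse decimation (up to a fraction of
vertices) so replicates need not share vertex counts or correspondence —
as real re-segmentations do not. Each replicate draws from an independent
substream derived from the master seed (`derive_seed()`), so results are
reproducible and order-independent.

**Full path (synthetic CT).** `rasterize_volume()` voxelizes the phantom
(inside test by ray-casting parity), assigns bone/background intensities
(defaults 400/0 HU-like units), applies separable Gaussian blur with
in-plane FWHM equal to the voxel spacing and axial FWHM equal to the slice
thickness (partial-volume model), and adds Gaussian image noise with
$\mathrm{SD} = \sigma_\mathrm{ref}/\sqrt{\text{exposure fraction}}$ — the
Gaussian approximation of Poisson photon statistics, under which halving
the exposure multiplies the noise SD by $\sqrt 2$.

**Segmentation.** `segment()` mirrors a semi-automatic bone chain:
threshold-connected region growing (6-connected), morphological closing
with a Euclidean ball (computed exactly through the Euclidean distance
transform, so anisotropic spacing is respected), hole filling, a signed
Euclidean distance map (negative inside, zero crossing on the mid-plane
between adjacent foreground and background voxel centres), Gaussian
smoothing of the distance map as a stand-in for level-set refinement, and
iso-surface extraction by **marching tetrahedra**: each cube is split into
six tetrahedra around a fixed body diagonal, which is watertight and free
of the facial ambiguities of plain marching cubes, at the cost of somewhat
more triangles. Observer variability is emulated by perturbing the
region-growing threshold per replicate (`threshold_jitter_sd`), the only
free parameter of the chain an operator actually controls.

## Numerical choices

* Nearest neighbours use a uniform grid hash with expanding ring search;
  ties resolve to the lowest vertex index. Exactness is tested against a
  brute-force all-pairs oracle.
* The distance transform is the exact separable lower-envelope algorithm,
  so morphology and signed distances carry no grid-approximation error
  beyond voxelization itself.
* KS statistics are computed on the exact pooled support, not a grid, and
  are tested against an exhaustive ECDF scan and against
  `stats::ks.test()`.
* All stochastic steps are seeded through one master seed with
  deterministic substream derivation; every study writes a manifest that
  is itself a valid configuration, so a run can be regenerated
  bit-identically from its own output.

## Parameter recovery and the choice of validation phantom

For validation, replicates of a radius-80 mm icosphere at subdivision 5
(10 242 vertices, mean edge length about 2.6 mm) are perturbed with
$\sigma$ between 0.05 and 0.5 mm. Since each nearest-neighbour distance
pools two independent per-point offsets, the mean balanced SD divided by
$\sqrt 2$ should recover $\sigma$; it does so within 10 %, monotonically.
The phantom size is an *a priori* geometric requirement, not a tuned
number: recovery needs vertex spacing well above the displacement scale so
that the nearest vertex is the true counterpart; when spacing approaches
the displacements, nearest-neighbour clipping biases the estimate low, as
expected from the underestimation property above.

## Worked example

```{r, eval = FALSE}
library(meshprecision)
base <- make_base_shape("sphere", 50, 5)
reps <- perturb_replicates(base, 5, noise_spec(0.1, seed = 1))
field <- balanced_sd(reps)
fraction_table(field)
ks_compare(field, balanced_sd(perturb_replicates(
  base, 5, noise_spec(0.2, seed = 2))))
```

Full studies are described declaratively (YAML or JSON; see
`system.file("extdata", "study.yaml", package = "meshprecision")`) and run
with `run_study()` or the bundled command-line driver in
`system.file("scripts", "meshprecision", package = "meshprecision")`.

## Limitations

* Phantoms are smooth closed surfaces; real bones have thin plates,
  contacting joint surfaces and internal trabecular structure that this
  generator does not model.
* The noise model is stationary Gaussian; real CT noise is correlated and
  object-dependent, and beam hardening or metal artefacts are out of
  scope.
* The KS p-value ignores spatial correlation between vertices (see above).
* Nearest-neighbour correspondence bounds displacement from below; for
  meshes whose vertex density is high relative to the deviations, the
  reported SD underestimates the true spread.
* There is no computational analogue of a human observer; observer
  variability is reduced to threshold perturbation by design.
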