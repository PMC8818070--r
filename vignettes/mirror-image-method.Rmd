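---
title: "Mirror-image background definition for FET PET: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mirror-image background definition for FET PET: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The quantification model

Amino-acid PET quantification in glioma works on ratios, not raw uptake.
For a voxel value $S(v)$ in SUV units and a background reference mean
$\bar S_{\mathrm{CTRL}}$, the tumour-to-brain ratio is
$\mathrm{TBR}(v) = S(v) / \bar S_{\mathrm{CTRL}}$, and the biological
tumour volume (BTV) is the connected component, containing the reader's
seed, of $\{v : \mathrm{TBR}(v) \ge 1.9\}$ inside the brain mask. The
whole analysis therefore stands or falls with
$\bar S_{\mathrm{CTRL}}$: a reference region drawn a little differently
moves the normaliser, which moves the effective SUV cut-off
$1.9\,\bar S_{\mathrm{CTRL}}$, which moves the BTV.

The mirror-image (MI) method makes the reference region a *function of the
tumour itself*. Starting from a single seed, an initial segmentation
$\mathrm{BTV}_0$ is grown on the SUV image at threshold 2.2 (a published
cut-off for recurrent glioma identification). Each iteration $k$ then:

1. reflects $\mathrm{BTV}_k$ across the mid-sagittal midplane,
   removes any voxels overlapping $\mathrm{BTV}_k$ and clips to the brain
   mask, giving $\mathrm{CTRL}_k$;
2. computes $\bar S_k$ over $\mathrm{CTRL}_k$ and forms the TBR map
   $S / \bar S_k$;
3. grows $\mathrm{BTV}_{k+1}$ from the same seeds on that map at
   threshold 1.9.

Iteration stops when
$|\,\mathrm{vol}(\mathrm{BTV}_{k+1}) - \mathrm{vol}(\mathrm{CTRL}_k)\,|
\le 0.2\ \mathrm{cm}^3$. After convergence the reference VOI is recomputed
by overlap removal against the final BTV and the reported
$\bar S_{\mathrm{CTRL}}$ comes from that post-exclusion VOI. The mirrored
region matches the tumour in size, shape and (reflected) location, so the
reference tissue composition mirrors the tissue the tumour occupies —
the argument for why this normaliser is less biased than an arbitrarily
placed VOI.

The guided crescent-shape (gCS) comparator is the linear version of the
same model: $\bar S_{\mathrm{CTRL}}$ comes from a reader-drawn crescent
VOI, the image is normalised once, and the BTV is grown once. Nothing
feeds back, so every drawing difference propagates into the BTV.

## Why variability collapses to zero

A threshold-connected component is fully determined by the map, the
threshold and *which component* the seed selects. Two seeds inside the
same lesion select the same component, so $\mathrm{BTV}_0$ — and by
induction every later quantity — is identical. The package tests this
seed-invariance at the primitive level (any voxel of a grown region
regenerates the identical region) and end-to-end (six random in-lesion
seeds give bitwise-identical results). This is the mechanism behind the
method's median intra-reader CoV of 0% on both background SUV_mean and
BTV; the gCS comparator inherits the reader's crescent variability
instead.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `suv_threshold` | 2.2 | SUV | initial growth cut-off for BTV₀ |
| `tbr_threshold` | 1.9 | TBR | BTV growth cut-off on the normalised map |
| `volume_tolerance_cm3` | 0.2 | cm³ | convergence band between vol(BTV) and the previous CTRL volume |
| `max_iterations` | 50 | – | cap; exceeding it returns `converged = FALSE`, never a silent answer |
| `connectivity` | 26 | – | 3D neighbourhood for region growing (6 available) |
| `exclude_suprabackground` | off | – | also strip supra-TBR voxels from the final CTRL VOI |

The two thresholds and the tolerance are the published operating point of
the method and should only be changed for other tracers or indications.
26-connectivity is the default because PET uptake blobs are smooth and
often obliquely contiguous at coarse voxel sizes; 6-connectivity is
offered for strict face adjacency. Threshold comparison is inclusive
(≥), which makes boundary voxels reproducible. `exclude_suprabackground`
extends the overlap removal to *any* supra-threshold TBR voxel in the
reference VOI (protecting against contralateral infiltration that is
disconnected from the seeds); it is off by default because the core
procedure removes only BTV overlap.

## Numerical and design choices

* **Convergence comparison.** The loop compares the *new* BTV volume with
  the *previous* iteration's CTRL volume. The trace (`tidy()` on an
  `mi_result`) exposes both sequences per iteration so the alternative
  reading (consecutive BTV volumes) can be audited on any run.
* **Post-convergence order.** Overlap removal happens once more against
  the final BTV, then statistics are extracted. The TBR map is *not*
  rebuilt for a further regrow after that exclusion: growth stops at
  convergence. (On symmetric backgrounds the exclusion does not change
  the mean, so the distinction only matters for pathological inputs.)
* **Mirroring convention.** Index $i$ along the midline axis maps to
  $N + 1 - i$ (1-based). An even-sized axis reflects about the inter-voxel
  midplane; an odd-sized axis keeps its central slab fixed. The operation
  is an involution and preserves voxel count, both enforced by tests.
* **Brain clipping of the mirror.** Mirrored voxels falling outside the
  brain mask are removed, since a reference region must be plausible
  tissue. Phantoms are built mirror-symmetric in the brain mask, so on
  synthetic data this clipping is a no-op.
* **Degenerate inputs fail loudly.** A lesion straddling the midline whose
  mirror is consumed entirely by the overlap removal raises
  "reference region fully excluded" (with the iteration index); a seed in
  sub-threshold tissue names the seed; a crescent VOI leaking outside the
  brain is rejected, not clipped. Oscillating (two-cycle) BTV volumes are
  detected and warned about, and hitting `max_iterations` flags the
  result rather than returning it as converged.
* **Coordinates.** All voxel coordinates, including seed files, are
  1-based — the native R array convention — and documented as such in the
  I/O functions.
* **ICC.** ICC(2,1) (two-way random effects, absolute agreement, single
  measurement) is computed from the two-way ANOVA mean squares, with
  McGraw–Wong F-based 95% intervals using Satterthwaite degrees of
  freedom, matching the behaviour of the widely used Python `pingouin`
  implementation; the point estimate is property-tested against an
  independent `aov()`-based oracle on random matrices. Reliability bands:
  poor < 0.5 ≤ moderate < 0.75 ≤ good ≤ 0.9 < excellent.
* **CoV.** The coefficient of variation uses the sample (n−1) standard
  deviation. With six repeats the n vs n−1 choice changes CoV by roughly
  10% relative, so it is pinned here and in the tests.
* **Paired tests.** MI-vs-gCS comparisons (per-reader Wilcoxon
  signed-rank, pooled Mann–Whitney U, two-tailed, α = 0.05) call
  `stats::wilcox.test`; the package validates their inputs but does not
  reimplement them.

## The synthetic phantom: what it does and does not emulate

Patient scans of this kind are not redistributable, so the package ships a
generator whose defaults define the standard study conditions: a
64 × 80 × 56 grid at 2 mm spacing; an ellipsoidal brain (semi-axes
55 × 70 × 45 mm) mirror-symmetric about the first-axis midplane;
background SUV 1.0 with optional additive Gaussian noise (clipped at 0);
one spherical lesion of radius 10 mm at SUV 3.0, centred 25 mm off the
midline. These values keep both thresholds active (lesion SUV 3.0 > 2.2;
lesion TBR 3.0 > 1.9 at background 1.0) and the mirrored reference inside
clean tissue, which is the geometry the method assumes. An optional rim of
intermediate uptake around the lesion (e.g. SUV 2.0, between the two
thresholds) exercises the difference between the SUV-grown BTV₀ and the
TBR-grown BTV and gives crescent contamination something to contaminate
with.

The simulated reader study mirrors the published design — 7 readers × 6
repeats — with seeds sampled uniformly over supra-threshold lesion voxels
and crescents built as jittered contralateral shell segments restricted to
a few axial slices, optionally swapping a binomial fraction of voxels for
rim voxels. All randomness flows from one top-level seed through
deterministic per-(reader, repeat) sub-seeds, so partial reruns reproduce
full runs.

What the phantom deliberately does **not** model: grey/white-matter
contrast, venous sinuses and patient-specific uptake gradients; correlated
PET noise textures and partial-volume effects; tumours that destroy
contralateral anatomy. Consequently, passing tests demonstrate the
*algorithmic* claims — determinism, seed-invariance, convergence, the
direction of the MI-vs-gCS variability contrast — not clinical accuracy on
real anatomy. The published gCS CoV magnitudes (driven by human drawing
behaviour) are reader-dependent and are not reproduced quantitatively,
only directionally: any nonzero crescent perturbation makes gCS CoV
strictly positive while MI CoV stays exactly zero.

Problem sizes used throughout the test-suite and the acceptance script —
the default phantom grid, 7 × 6 reader studies, 20 randomised convergence
phantoms, 100 random ICC matrices — were chosen as the smallest sets that
exercise every claim with comfortable margins.

## Known limitations

* Tumours heavily involving the anterior–posterior midline, bilateral
  multifocal disease and anatomy-destroying growth are out of scope by
  design: the pipeline raises errors rather than approximating a reference
  region.
* Inputs must be brain-extracted, SUV-calibrated and rigidly aligned so
  the mid-sagittal plane is a grid-axis midplane; the package documents
  and assumes, but does not perform, that pre-processing. The
  `midline_axis` argument covers data whose sagittal axis is not the
  first array axis.
* One phantom is one "patient": inter-patient statistics (ICC across
  targets) need studies over several phantoms, which the reliability
  module supports but the single-phantom convenience path reports as NA.
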