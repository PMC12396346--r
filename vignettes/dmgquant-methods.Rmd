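---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models, the tunable parameters
that matter, the behavior of the synthetic-data generators, and the
numerical choices made where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## Single-cell cell-state pipeline

### Filtering and normalization

Cells are retained when their number of detected genes (entries > 0)
meets a platform-dependent minimum: 2000 for plate-based smart-seq2
libraries, 1000 for droplet/UMI libraries. We read "cutoff" as the
minimum acceptable value, so the boundary is inclusive; both cutoffs are
arguments of `filter_cells()`. Gene filtering keeps the `k = 7000` genes
of highest mean expression; boundary ties are broken by gene-id
lexicographic order so results never depend on storage order.

Normalization maps counts to CPM per cell and every entry to
`log2(v/10 + 1)`. The division by 10 deliberately rescales the nominal
10^6 of C/TPM toward a realistic per-cell complexity of ~10^5, so that a
pseudo-count of 1 sits at a sensible depth. The transform is strictly
monotone and maps 0 to 0; both properties are tested. Centering
(`center_within_sample()`) subtracts each gene's mean within each sample
independently and is idempotent.

### Signature scores with bin-matched controls

The scoring function's internals are a documented convention, not a
reproduction of any published code: genes are ranked by mean expression
within the sample and split into `n_bins = 30` equal-size bins; for each
signature gene, `n_ctrl = 100` control genes are sampled (seeded, without
replacement when the bin allows, signature genes excluded from the pool)
from its bin; the score is the mean centered expression over the
signature minus the mean over the pooled control multiset. Control
subtraction cancels the dependence of centered means on per-cell
complexity. `n_ctrl = 0` disables the subtraction — the right setting for
toy matrices whose bins would hold a handful of genes.

All scoring and centering is per sample: each sample's own gene means
define both the centering and the bins. The RNG is re-seeded identically
for each sample, which yields two useful invariants checked in the tests:
scores are unchanged under cell-order permutation, and a duplicated
sample receives identical scores in both copies.

### The stemness–lineage map

With per-cell scores for the OPC-like, OC-like and AC-like states,

* stemness = OPC − max(OC, AC),
* lineage = max(OC, AC), negated when AC is strictly the larger
  (an exact AC = OC tie counts as OC, since the sign flip applies only
  when the AC score is higher),
* when both OC and AC are negative the cell has no meaningful
  differentiated direction: lineage is 0 plus seeded uniform jitter in
  [−0.05, 0.05] and the row is flagged `jittered`.

The jitter half-width is not specified by the source methodology beyond
"some jitter"; 0.05 is small relative to the score scale (the simulated
state effect of 1 produces own-state scores of order 1) and is a
configurable argument. Receptor-high cells for map highlighting are those
with centered expression strictly greater than 1.

### Correlation screening

Within-sample screening computes Pearson r between the per-cell score and
each gene's expression inside every sample with at least 3 cells, then
averages r arithmetically across samples — no Fisher z-transform, because
the quantity being reproduced is a plain average of correlation values.
Across-sample screening correlates pseudo-bulk sample scores with
pseudo-bulk expression within each study (≥ 3 samples) and averages
across studies. Pseudo-bulk is the mean of pre-log CPM over malignant
cells per sample, then the same log transform, with no centering.
Spearman is available as an option where rank-based robustness is wanted;
Pearson is the default. Zero-variance samples/genes are skipped with
warnings rather than producing NaN.

FDR control is Benjamini–Hochberg step-up, implemented directly (sort
descending, scale by n/rank, running minimum capped at 1) and tested
against a brute-force oracle written from the definition; flags are
q < 0.05.

## Photometry pipeline

The processing order is: bleach fit → subtraction → baseline z-score →
LOESS (visualization) → windowed AUC of the *unsmoothed* z-score. The
z-score-then-smooth order follows the natural reading of the source
processing description; `auc_on = "z_smooth"` flips the AUC onto the
smoothed curve for users who want the other order.

**Debleaching.** Both `A·e^(−t/τ) + C` and
`A1·e^(−t/τ1) + A2·e^(−t/τ2) + C` are fitted by nonlinear least squares
with deterministic data-driven starts (amplitude from the first-to-last
drop, offset from the final value, time constants at span/3, or span/10
and span/2). The model with lower corrected AIC wins; a `model` argument
overrides. Numerical choices worth knowing:

* Fits run on the standardized trace and parameters are mapped back.
  This makes the whole debleach + z-score pipeline *exactly* equivariant
  under affine rescaling `F → aF + b` (a > 0) — the optimizer sees
  byte-identical inputs — and the tests verify invariance to ~1e-13 for
  the mono path.
* Time constants are bounded above at 10× the trace span. A slower decay
  is unidentifiable against the offset over the recording and produces a
  degenerate fit valley in which the optimizer's stopping point is
  arbitrary.
* A Levenberg-damped Gauss–Newton polish with analytic Jacobians runs
  after `nls`, so the solution is at machine precision rather than at the
  generic optimizer's default tolerance.
* When corrected AIC *marginally* prefers the bi model on data whose true
  bleach is mono (it absorbs a transient event or noise structure), the
  slow component is near-collinear with the offset and limits affine
  reproducibility to ~1e-5. This is a conditioning property of the
  selected model, not of the pipeline; the test suite asserts the strict
  bound on the well-conditioned mono fit and a conditioning-limited bound
  for the marginal-bi case.
* Debleaching subtracts the fitted curve rather than dividing by it: the
  subsequent z-score makes the two equivalent up to the bleach-varying
  variance, and subtraction cannot blow up on a near-zero fitted offset.

**Z-scoring** uses mean and SD over the baseline window (≥ 10 samples,
positive variance enforced); `sd_source = "full"` substitutes the
whole-trace SD for recordings whose baseline is too quiet. **LOESS** is
degree-1 tricube local regression over a `frac = 0.1` span with no
robustness iterations (backed by the C implementation in
`stats::lowess`, `delta = 0` for exactness); with `frac = 1` every local
fit uses all points, weighted from the evaluation point, which the tests
check against explicitly weighted `lm` fits. **AUC** snaps window
endpoints to the nearest sample and integrates inclusively, which makes
the integral exactly additive over adjacent windows sharing a boundary
sample. The isosbestic 405 nm channel is not part of the described
processing and is not modeled.

## Puncta pipeline

**Background subtraction** is a grayscale morphological opening per
z-plane over a disk whose radius is given in micrometers and converted
via the in-plane voxel size. A true "ball" structuring element needs an
intensity-to-pixel scale that is arbitrary for floating-point microscopy
data (ImageJ resolves it by internal rescaling that the source script
does not document); the flat disk is scale-free, maps constant planes to
zero exactly and preserves any blob narrower than the disk essentially
exactly, which is the behavior the pipeline needs before detection.
Output is clipped at zero.

**Detection** is a difference of Gaussians at scales σ and kσ (k = 1.6),
with each σ converted per axis to voxels so anisotropic confocal stacks
(e.g. 0.15 μm z steps vs 0.1 μm in plane) are filtered isotropically in
physical space. The response is normalized so an ideal Gaussian blob of
scale σ and peak amplitude A responds with ≈ A, making `min_peak`
comparable across scales. Peaks are strict 26-neighborhood maxima at
voxel centers — no subpixel refinement, so localization accuracy is half
a voxel — and maxima within one σ of any border are discarded as
unresolvable.

**Colocalization** is the percentage of postsynaptic puncta whose nearest
presynaptic punctum lies within 1.5 μm, 3D Euclidean in micrometers
(inclusive boundary; a `projection = "2d"` mode ignores z). The default
implementation hashes presynaptic points into a uniform grid with cell
edge equal to the threshold and inspects 27 cells per query — exact for
the within-threshold decision — and is tested for exact agreement with
both an in-package exhaustive mode and a naive all-pairs oracle in the
test suite.

## What the simulators emulate — and what they do not

The generators' defaults are the stated world of the test surface, chosen
once:

* **Expression**: 300 cells, 3 samples, 2000 genes, 50 signature genes
  per state, state effect 1.0 (e-fold), mean library 5000 counts,
  NB dispersion 0.1 — a small droplet-style experiment in which state
  structure is clearly present but not trivial. Cells are assigned to
  samples round-robin so every sample contains all states (the unit of
  analysis is within-sample). The designated receptor gene shares the
  OPC shift without belonging to any signature, emulating a receptor
  whose expression tracks a state. *Not* emulated: ambient RNA, doublets,
  batch effects, platform-specific noise — a green test establishes
  correctness of the scoring arithmetic and its statistical behavior
  under the stated model, not robustness to sequencing artifacts.
* **Photometry**: 10 min at 20 Hz, mono bleach (A = 5, τ = 60 s, C = 1),
  events with instant rise and 2 s decay, noise SD 0.05. The instant-rise
  kernel has the closed-form window integral `A·τ(1−e^(−T/τ))` used as an
  oracle. Hardware demodulation and motion artifacts are out of scope.
* **Puncta**: 20×20×5 μm field, 150/100 puncta, colocalized fraction 0.4
  with 0.2 μm placement jitter, 0.3 μm blobs at SNR 10 on confocal-like
  voxels. Rendering uses isotropic Gaussian blobs — no PSF tails, no
  chromatic shift. Note that colocalization estimates always include the
  chance rate of the point density; the tests compare against truth plus
  a Monte-Carlo chance-rate oracle, and sparse geometries (larger
  volumes) are used where the chance rate must be small.
* **Cell records**: 6 fields × 170 cells (≈ 1000 cells per coverslip, the
  magnitude of the source counting scheme), EdU Bernoulli at the
  configured rate.

One test-world choice deserves a note: the rendered two-channel
colocalization test uses a 6 μm z extent rather than the 5 μm default.
With a thin stack, the one-σ border-discard shell occupies a large
fraction of the volume and uniform placement systematically drops the
presynaptic partner of border-straddling pairs — a geometry artifact,
not a property of the quantification under test.

## Degenerate inputs and tie-breaks (summary)

* Constant photometry trace → mono fit with A = 0, C = the constant.
* Sample with one cell → centers to zero, with a warning.
* AC = OC exactly → lineage takes the OC (positive) sign.
* Gene-filter ties → lexicographic gene id.
* Empty presynaptic set → 0% with a warning; empty postsynaptic set →
  error (the ratio is undefined).
* Zero-denominator fields → excluded with a warning; all excluded →
  error.
* Pooled vs field-mean proliferation indices are both reported and are
  different statistics: pooled is cell-weighted (Σnum/Σden), field-mean
  weights fields equally as the systematic center/margin sampling scheme
  does.

## Known limitations

* The OPC/OC/AC signatures are inputs; the package ships no gene lists
  (the real ones are defined in external publications), and the tests use
  synthetic signatures with known coupling.
* DoG detection reports voxel-center coordinates; subpixel refinement and
  deconvolution are out of scope.
* The correlation screen treats samples and studies as exchangeable units
  and averages r arithmetically; no weighting by sample size and no
  meta-analytic variance model.
* No malignancy inference, CNV calling, clustering or batch correction:
  malignancy flags and sample labels are trusted inputs.
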