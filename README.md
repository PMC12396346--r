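# dmgquant

Quantification pipelines for studies of neuronal-activity-driven diffuse
midline glioma (DMG) growth, packaged as tested, reusable R functions.

Studies of neuron–glioma interaction combine four very different kinds of
quantification, usually implemented as one-off scripts: single-cell
RNA-seq cell-state scoring, fiber-photometry signal processing, confocal
synaptic-puncta colocalization, and simple tabular assay metrics.
`dmgquant` implements each as a documented module with a synthetic-data
generator that produces every input with known ground truth, so the whole
surface is testable offline, without any dataset download.

## What the package computes

**Single-cell cell-state scoring (`sc_state`).** Cells are filtered by
detected genes (≥ 2000 for smart-seq2, ≥ 1000 for UMI platforms), genes by
mean expression (top 7000), and expression is normalized as

    E = log2(CPM/10 + 1)

(the division by 10 reflects a realistic per-cell complexity of ~100,000
rather than the nominal 10^6 of CPM/TPM). Signature scores for the three
malignant states (OPC-like, OC-like, AC-like) are the mean centered
expression over the signature genes minus a bin-matched control-gene mean
(30 expression bins, 100 controls per gene, seeded), computed per sample.
The 2D cell-state map is

    stemness = OPC − max(OC, AC)
    lineage  = ±max(OC, AC)   (negative iff AC > OC; jittered near 0 when both < 0)

with receptor-high cells flagged by centered expression > 1 (e.g. *CHRM1*,
*CHRM3*). Gene–state association is screened by within-sample Pearson
correlation of expression with the OPC score (averaged across samples) and
across-sample pseudo-bulk correlation per study (averaged across studies),
with Benjamini–Hochberg FDR control.

**Fiber photometry (`photometry`).** Traces are debleached by mono- or
bi-exponential least squares (corrected-AIC model selection), z-scored
against a baseline window, LOESS-smoothed (fraction 0.1) and summarized by
the trapezoidal AUC of the z-score over analysis windows (pre / during /
post stimulation).

**Synaptic puncta (`puncta`).** Per-plane rolling-ball-style background
subtraction, difference-of-Gaussians peak detection in anisotropic
physical coordinates, and the colocalization percentage: the fraction of
postsynaptic (CHRM1/3, glioma) puncta whose nearest presynaptic (VAChT,
neuron) punctum lies within 1.5 μm (3D Euclidean distance).

**Assay metrics (`assay_metrics`).** EdU proliferation indices
(EdU⁺/DAPI⁺, EdU⁺/HNA⁺, EdU⁺/GFP⁺ — per field, pooled, and field-mean) and
spheroid migration ratios normalized to the time-zero invasive diameter.

**Synthetic data (`synthetic_data`).** Negative-binomial 3-state
expression matrices with state-coupled signature genes and a designated
receptor gene; photometry traces (exponential bleach + transient events +
Gaussian noise, with analytic event integrals); 3D puncta fields with a
known colocalized fraction (optionally rendered as Gaussian-blob stacks);
Bernoulli EdU cell records. All seeded and deterministic.

## Worked example

```r
library(dmgquant)

## single cell: simulate, score, map
sim  <- gen_expression(sc_sim_config(n_cells = 300, n_samples = 3,
                                     state_effect = 1.0, seed = 42))
mlog <- normalize_log(sim$matrix)
tbl  <- stemness_lineage(state_scores(mlog, sim$signatures, seed = 42),
                         seed = 42)
head(tbl[, c("cell_id", "opc_score", "stemness", "lineage", "jittered")], 3)
#>     cell_id  opc_score  stemness    lineage jittered
#> 1 cell00001  1.2015166  1.355824 0.04148060     TRUE
#> 2 cell00002 -1.0284268 -2.152689 1.12426220    FALSE
#> 3 cell00003  0.9858489  1.324948 0.04370754     TRUE

mean(tbl$stemness[sim$true_state == "OPC"])   # 1.505
mean(tbl$stemness[sim$true_state != "OPC"])   # -2.093

## receptor gene vs OPC score, within samples
opc <- signature_score(mlog, sim$signatures$OPC, seed = 42)
cen <- center_within_sample(mlog)
correlate_within_samples(cen, opc, genes = sim$receptor_gene)
#>        gene    mean_r n_samples all_skipped
#> 1 gene00151 0.3754579         3       FALSE

## photometry: bleach fit, z-score, windowed AUC
ph   <- gen_photometry(photo_sim_config(duration = 240, fs = 10,
                                        event_times = 125,
                                        event_amplitude = 1.5, event_tau = 5,
                                        noise_sd = 0.25, seed = 42))
sess <- process_session(ph$trace,
                        windows = list(pre = c(20, 120),
                                       during = c(125, 225)),
                        baseline_window = c(0, 120))
sess$auc
#>   window start end        auc
#> 1    pre    20 120 -0.9717517
#> 2 during   125 225 18.3076341

## puncta: colocalization with known ground truth (40% + chance rate)
pn <- gen_puncta(puncta_sim_config(volume = c(50, 50, 20),
                                   n_neuron_puncta = 200,
                                   n_glioma_puncta = 500,
                                   colocalized_fraction = 0.4, seed = 42))
coloc_percentage(pn$glioma, pn$neuron, threshold = 1.5)
#> ColocResult: 219 / 500 puncta within 1.5 um (43.80%)
```

The cell with a true OPC state scores high on stemness; the state-coupled
receptor gene correlates positively with the OPC score in every sample;
the AUC during the stimulus window dwarfs the pre-stimulus AUC; and the
observed 43.8% colocalization is the simulated 40% plus the chance rate of
the point density (~4.8% here).

A command-line interface covers the same pipelines; see `?dmgquant_cli`:

```sh
Rscript exec/dmgquant simulate sc --seed 1 --out simdir
Rscript exec/dmgquant scstate run --matrix simdir/matrix.mtx \
    --meta simdir/cells.tsv --signatures simdir/signatures.gmt \
    --receptors gene00151 --out outdir
```

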