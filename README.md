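# plexcell

Cell typing and quality control for multiplexed (isobaric/TMT-style)
single-cell proteomics.

Single-cell proteomics of immune cells measures a few tens of picograms of
peptide per cell across dozens of reporter-ion channels per LC-MS run. The
resulting matrices are shallow, sparse, batch-structured, and carry two
characteristic artifacts: background signal bleeding from heavily loaded
bridge (reference) channels into empty channels, and duplicate "low-content"
cell populations created by cells that leaked cytosolic protein through
unintentional permeabilization before isolation. `plexcell` implements a
complete analysis path for such data:

- **Containers and I/O** — `QuantMatrix` (a `SummarizedExperiment` of
  features × samples with explicit missingness, level and scale tags),
  `PlexDesign` (channels, roles, bridge inputs), readers/writers for wide
  TSV/CSV tables, metadata TSV and design JSON.
- **QC and input estimation** — per-channel summed intensities and
  identification counts, role fold differences, data completeness,
  cumulative/local sensitivity curves, and back-calculation of each cell's
  peptide input: `input_pg = bridge_pg × cell_sum / bridge_reference`,
  anchored on bridge channels of known load (e.g. 150 pg each).
- **Normalization** — median normalization on log2 intensities; an NA-aware
  empirical-Bayes location/scale batch correction (the ComBat model:
  per-feature standardization, per-batch additive γ and multiplicative δ
  effects shrunk toward normal / inverse-gamma priors estimated by method
  of moments, then back-transformation — missing cells stay missing);
  k-nearest-sample or low-value imputation for analyses requiring complete
  data.
- **Reference label transfer** — highly variable feature selection, feature
  overlap with a transcriptome reference, PCA projection with
  distance-weighted k-NN voting producing per-cell prediction scores
  (rows sum to 1), and a data-driven confidence cutoff
  `mean(max score) − 1 SD`.
- **Hybrid annotation** — PCA → shared-nearest-neighbor graph (Jaccard
  edge weights) → Louvain clusters from the proteomic data alone; each
  cluster is labeled by hypergeometric enrichment `P(X ≥ k)` with
  `X ~ Hypergeom(N, K, n)` over high-confidence cells only, the winning
  label is propagated to **all** cluster members, and clusters without an
  enriched type become `"unknown"`. Same-label cluster pairs are screened
  for permeabilization (median input ratio ≤ 0.67 plus rank-sum tests on
  estimated input and identification counts); flagged clusters are removed
  and annotation is re-run on the retained cells.
- **Differential abundance** — one-vs-rest moderated t per protein and
  cell type: pooled two-sample statistics on observed values only,
  empirical-Bayes variance shrinkage
  `s̃² = (d₀·s₀² + d·s²)/(d₀ + d)` with `(d₀, s₀²)` estimated by method of
  moments on `log s²`, two-sided p-values, Bonferroni correction within
  each contrast.
- **Synthetic data** — a ground-truth generator (type-structured
  proteomes, log-normal per-cell inputs, bridge/blank channels, batch
  effects, permeabilization leak) plus an acquisition simulator with a
  per-run MS2 scan budget that compares standard intensity-biased
  precursor selection against library-gated ("real-time search"-style)
  selection, including bridge-driven interference in blank channels.

## Worked example

```r
library(plexcell)
report <- runPipeline(defaultRunConfig(seed = 17))
print(report)
```

```
RunReport
  cells: 540 analyzed, 395 retained, 145 flagged permeabilized
  completeness 0.70 | median input 12.6 pg | 261 proteins
  folds: bridge/cell 11.9, cell/blank NA
  labels: T1=91, T2=76, T3=84, T4=61, T5=83 
  truth: accuracy 0.977 | perm recall 0.642 | markers top-decile 1.000
  elapsed: 9.5 s
```

The default run simulates 20 batches of a 32-plex layout (2 bridge
channels at 150 pg, 3 blank channels, 27 single cells of ~14 pg median
input; six cell types including a rare granulocyte-like population absent
from the reference), acquires them with library-gated selection, and runs
the full pipeline. The report shows: cells retained after
permeabilized-cluster removal; single-cell data completeness; the median
back-calculated peptide input; the bridge:cell fold difference of median
summed intensities (blank channels are mostly empty here, so the
cell:blank fold is undefined); propagated label counts; and — because the
truth is known — annotation accuracy on retained cells, the recall of
planted permeabilized cells, and the fraction of planted type markers
ranking in the top decile of moderated t for their own contrast.

Individual stages run standalone (`channelSums()`, `estimateInput()`,
`medianNormalize()`, `combatAdjust()`, `imputeMissing()`,
`transferLabels()`, `snnGraph()`, `louvainCluster()`,
`clusterEnrichment()`, `flagPermeabilized()`,
`runDifferentialAbundance()`), and
`inst/scripts/run_pipeline.R` is a shell entry point around
`runPipeline()`.

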