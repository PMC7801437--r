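# mitocell

Single-cell RNA-seq tools for discovering **mitochondrial expression
sub-populations** and characterising their **mitochondrial RNA
mutational landscape**.

Pancreatic beta cells (and other cell types) split into two
sub-populations that differ in the expression of the 13 mtDNA-encoded
OXPHOS protein genes — designated **HE** (high expression) and **LE**
(low expression). `mitocell` re-implements, as a tested and reusable R
pipeline, the full analysis that discovers and characterises this
split:

* **QC** — cell filters on detected genes, ribosomal fraction
  (≤ 20%), non-zero mtDNA, INS/GCG marker doublets, and a
  dataset-level mtDNA over-representation rule (10% fixed, 2× median,
  or median + 2 SD of mtDNA read counts).
* **Clustering** — PCA of the platform-appropriate mtDNA
  protein-coding gene set (all 13 genes for Fluidigm C1/CEL-Seq2; 9
  of 13 for human inDrops, which censors short-poly-A transcripts),
  shared-nearest-neighbour graph + Louvain communities on the first
  two PCs over a 0.1–1 resolution scan, HE/LE labels by mean mtDNA
  expression, and a cross-scope **retention** statistic.
* **Differential expression** — negative-binomial GLM LRT (shared
  ML dispersion, 1 df), the zero-inflated "bimodal" LRT (χ², 2 df),
  a jackknife-resampled Wilcoxon rank-sum test for uneven group
  sizes, one-way ANOVA, and BH-FDR control, plus a random-gene
  resampling control (100 genes × 1000 draws).
* **Mutations** — strand-aware heterogenic variant calling from
  samtools-mpileup text: depth ≥ 400, ≥ 2 reads per strand, not
  read-end-only, frequency > 1%, coding region only, cells with
  ≥ 1000 well-covered positions. A permutation **mutational
  repertoire** statistic (1000 positions × 1000 iterations per cell),
  unique/overlapping mutation partitions, and candidate-**inherited**
  classification through alpha-cell sharing.
* **Conservation** — mean phastCons-style score at mutation positions
  against a 10,000-iteration resampling null: observed/expected
  ratio with a direction-adaptive empirical p.
* **Synthetic data** — seeded generators with planted ground truth
  for count matrices (NB + dropout + co-shifted OXPHOS/markers),
  strand-resolved pileups with planted low-frequency variants, and
  conservation tracks; every stage is validated against them.

## Worked example

```r
library(mitocell)

## two-population expression matrix, pileups with a 3x higher variant
## rate planted in HE cells, and a block conservation track
simc <- simulate_counts(sim_expression_config(
  n_cells_he = 60, n_cells_le = 60, seed = 1))
pv <- data.frame(
  position = c(seq(150, by = 120, length.out = 9),
               seq(210, by = 360, length.out = 3)),
  alt_base = "A", frequency = 0.05,
  group = rep(c("HE", "LE"), c(9, 3)), strand_balance = 0.5)
simp <- simulate_pileups(sim_pileup_config(
  mt_length = 1400, coding_region = c(51, 1350),
  n_cells = c(HE = 5, LE = 5), coverage_mean = 600, coverage_sd = 60,
  planted_variants = pv, seed = 2))
trk <- simulate_conservation_track(1400, c(0.2, 0.8, 0.4, 0.6),
                                   seed = 3, jitter_sd = 0.05)

cfg <- run_config(
  counts = simc$matrix, pileups = simp$pileups,
  pileup_groups = simp$truth$cell_groups, track = trk,
  qc = qc_config(min_genes_per_cell = 50),
  variant_qc = variant_qc_config(coding_region = c(51, 1350)),
  snn_k = 15, seed = 7)
summary <- run_pipeline(cfg)
print(summary)
print(summary$objects$mutations$repertoire)
```

prints

```
mitocell run summary
  cells: 120 in, 110 pass QC
  HE/LE: HE=61 LE=49, retention 1.000
  variant calls: 60 over 10 eligible cells
  conservation ratio: HE=1.074 LE=0.901
mutational repertoire (1000 iterations, 1000 positions/cell):
  HE   5 cells: 0.6956% +/- 0.0577%
  LE   5 cells: 0.2302% +/- 0.0315%
```

Reading it: QC removed 10 of 120 cells; the mtDNA-gene clustering
recovered a two-way HE/LE split whose labels are fully consistent
between per-individual and pooled scopes (retention 1.0); the variant
caller found 60 passing calls across the 10 eligible cells; and the
planted 3× variant-rate excess in HE shows up directly in the
repertoire statistic (0.70% vs 0.23% of resampled positions mutated).
The conservation ratios compare each subgroup's observed mean score
with its resampling expectation (values below 1 mean mutations sit at
less-conserved positions).

A command-line wrapper with the same stages lives at
`inst/exec/mitocell`
(`mitocell simulate|qc|cluster|de|mutations|conservation|run
--config <yaml> --seed <int> --outdir <dir>`).

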