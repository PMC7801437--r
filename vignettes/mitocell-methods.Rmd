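---
title: "mitocell: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitocell: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocell)
```

# What the package computes

`mitocell` analyses single-cell RNA-seq of (typically pancreatic beta)
cells along two coupled axes:

1. **Expression**: do cells split into sub-populations with high (HE)
   and low (LE) expression of the 13 mtDNA-encoded OXPHOS protein
   genes, and which nuclear genes co-vary with that split?
2. **Mutation**: do the two sub-populations differ in their
   mitochondrial RNA heterogenic mutations — the low-frequency minor
   bases visible in per-cell pileups — in burden (the *mutational
   repertoire*), in sharing, and in the evolutionary conservation of
   the positions they hit?

Everything runs from three inputs: a gene-by-cell integer count matrix
with per-cell annotations, per-cell samtools-mpileup text over the
mitochondrial genome, and a per-base conservation-score track
(phastCons-style, scores in [0, 1]).

# Quality control

Per-cell rules, all computed on raw counts:

* **Detected genes** — at least `min_genes_per_cell` genes with count
  > 0. The default 3000 reflects deep full-length platforms (Fluidigm
  C1, CEL-Seq2); shallow droplet data needs a lower value (500 is the
  package's suggestion for inDrops-like data, a documented assumption
  since no canonical value exists for such data).
* **Ribosomal fraction** — at most 20% of reads from RPS/RPL genes.
* **Non-zero mtDNA** — cells with zero mtDNA-gene counts are removed.
* **Marker doublets** — cells co-expressing both markers of two
  mutually exclusive cell types (INS and GCG by default) at or above
  `doublet_min_count` raw counts. The count threshold (default 5) is a
  package choice; the field typically eyeballs this, so it is exposed
  in `qc_config()`.

mtDNA *over*-representation (a stress/death signature) is handled by a
dataset-level rule computed on the cells that already pass the
per-cell rules: `fixed_10pct` (fraction > 10%), `twofold_median`
(mtDNA read count > 2x the dataset median), or `median_plus_2sd`
(count > median + 2 SD). The default is `median_plus_2sd`: the fixed
10% rule discards a large share of otherwise healthy high-mtDNA cells,
while the median-based rule keeps sample sizes up without admitting
outliers — the trade-off that motivated the same choice in the
analyses this package operationalizes.

Normalization is the standard log1p of counts per 10,000, followed by
per-gene centring/unit scaling; `regress_total = TRUE` replaces each
gene's scaled values with residuals of a linear fit on per-cell total
counts, removing the cell-complexity trend before clustering.

# Sub-population discovery

PCA is computed per individual (and pooled) on the scaled expression
of the platform-appropriate mtDNA gene set (`mtdna_gene_set()`): all
13 protein-coding genes for full-length platforms; for inDrops, genes
with short poly-A tails are excluded (human: ND5, ND6, ND4L, ATP8;
mouse: Nd4l, Atp8, Nd6) because poly-A selection censors them.

"Density clustering" is realized as the SNN-graph / modularity idiom
standard in this field: k-nearest neighbours (k = 20, Euclidean) on
the first two PCs, Jaccard edge weights pruned below 1/15, Louvain
community detection at a configurable resolution. Resolutions 0.1–1
are scanned; the package's policy — since no selection rule is
canonical — is the *smallest* resolution yielding exactly two
communities. When no grid value yields exactly two (common for weakly
separated data, where Louvain jumps from one community to three or
more), the pipeline falls back to the fewest-community solution with
at least two and merges communities into two super-groups by ranking
their mean normalized mtDNA expression and splitting at the largest
gap; the run summary flags this. The cluster with the higher mean
normalized mtDNA expression is labelled HE, the other LE, which also
makes HE/LE identity comparable across clusterings without solving a
label-matching problem.

**Retention** is the fraction of cells whose pooled-scope HE/LE label
equals their per-individual label. It is symmetric in the two
labelings and equals ~0.5 for independent random labels.

Marker genes between HE and LE are tested only when expressed in more
than 25% of cells of at least one group, with BH-FDR adjustment, and
benchmarked against a random-gene control: 100 random genes resampled
1000 times give the null distribution of per-draw significant counts.

# Differential-expression tests

* `negbinom_lrt()` — likelihood-ratio test of an NB GLM (log link)
  with a group term against intercept-only. The dispersion is
  estimated once by maximum likelihood under the alternative and
  shared by both models, keeping the test at 1 df. Without covariates
  the NB MLE means are the group sample means for any dispersion, so
  the profile likelihood is maximized directly (fast and exact); with
  per-cell totals the models are refit with a log-total offset via
  `MASS::glm.nb` / `MASS::negative.binomial`.
* `bimod_lrt()` — the zero-inflated ("bimodal") formulation for
  full-length platforms: an observation is zero with probability
  1 − π or Normal(μ, σ²) when expressed; the alternative allows
  group-specific (π, μ), σ is pooled over expressing cells and
  re-estimated under each hypothesis, and the statistic is referred to
  χ²(2). Re-estimating σ under the null (rather than freezing the
  alternative's estimate) is what keeps the test calibrated.
* `wilcoxon_jackknife()` — for uneven group sizes the larger group is
  subsampled to the smaller's size 1000 times and each resample gets a
  two-sided rank-sum test. The resample p-values are aggregated by
  their **median** (a package decision — no canonical aggregation
  exists; the mean is available via `aggregate = "mean"`). Equal-sized
  groups get a single test.
* `anova_oneway()` and `bh_fdr()` delegate to `stats::aov` and
  `stats::p.adjust(method = "BH")`.

All three bespoke tests hold their nominal type-I error (empirically
within [0.03, 0.07] at α = 0.05 over 1000 null simulations at
n = 100 + 100; see `test-acceptance.R`).

# Variant calling and the repertoire statistic

Pileups are parsed from the mpileup text dialect with full
strand/read-start/read-end accounting; indel spans and `N`/`*`/`<`/`>`
symbols count toward depth but never as substitutions, and records
whose declared depth disagrees with the decoded reads are rejected.
Base qualities are parsed but unused — the filters are
coverage/strand/position-based.

A non-reference base at a position is called iff (all thresholds in
`variant_qc_config()`):

* position depth ≥ 400 (inclusive — where "at least 400" and "> 400"
  both circulate, the inclusive reading is adopted and documented);
* ≥ 2 supporting reads on **each** strand;
* support is not exclusively from read ends (operationalized through
  the `$` read-end marks in the pileup text: a base whose supporting
  reads are all end-flagged is dropped);
* frequency (support / depth) strictly > 1%;
* the position lies in the protein-coding region (the D-loop is
  excluded for coverage reasons).

Each qualifying alt base is a separate call (one position can host two
mutations). Cells enter mutation analyses only with ≥ 1000
coding-region positions at calling depth.

The **mutational repertoire** of a subgroup is a permutation
statistic: per iteration (1000 total), 1000 high-quality positions are
drawn *without replacement* from each cell's pool, the drawn positions
carrying a called variant are summed over the subgroup's cells, and
the sum is divided by 1000 x the number of cells (x100 for percent).
Sampling without replacement makes the full-pool case exact — with
pools of exactly 1000 the statistic equals the closed-form percentage
in every iteration, which the tests assert to machine precision.
Variants are summed per cell before aggregation (two cells mutated at
the same position count twice), matching the per-cell framing of the
resampling.

**Inherited classification**: a beta-cell mutation (position + alt
base) also seen in ≥ 1 alpha cell of the same individual is a
*candidate inherited* mutation — presumed to predate lineage
separation — everything else `other`; subgroup tables report percent
inherited. Unique-versus-overlapping counts between HE and LE key on
(position, alt base) and partition the union.

# Conservation permutation test

The observed statistic is the mean conservation score at the
*deduplicated* mutation positions (a position set, not a call
multiset; multi-allelic positions count once). The null resamples the
observed number of positions 10,000 times without replacement from a
pool and averages each draw; the expected value is the mean over
iterations. The ratio observed/expected is reported with a one-sided
empirical p whose direction follows the ratio: the fraction of
iterations *below* the observed mean when the ratio < 1, *above* when
> 1.

Two deliberate choices:

* **The pool** is the coding-region positions covered at calling depth
  for the sample (the only universe in which a mutation could have
  been observed); `all_coding_positions` behaviour can be had by
  passing that range as the pool.
* **p = plain fraction** by default (so p = 0 is possible);
  `add_one = TRUE` gives the (k+1)/(N+1) correction.

A subtlety worth knowing: because the direction is chosen *after*
seeing the ratio, the reported p is uniform on (0, ½) under the null,
not on (0, 1) — the fixed-direction tail probability is the uniform
one. The tests check both facts.

For group comparison the pipeline computes, besides the per-subgroup
permutation test, a per-cell conservation ratio (the cell's observed
mean over the subgroup pool expectation) and feeds HE/LE ratios to
`anova_oneway()`; with several individuals the per-individual
subgroup ratios are the natural ANOVA units, but per-cell ratios keep
the comparison defined for a single individual.

# Synthetic data: what it emulates, what it does not

`simulate_counts()` draws NB counts (variance μ + φμ²) with log-normal
library-size factors and plants a two-component structure: HE cells
shift mtDNA genes by `mt_logfc` (natural log; default 1.5), nuclear
OXPHOS genes by `oxphos_logfc` and markers (INS, IAPP) by
`marker_logfc`. Baseline means put mtDNA at roughly 5% of LE-cell
reads and ~17% of HE-cell reads — the regime in which the QC
mtDNA-fraction rules are meaningful. GCG is present near-silent so the
doublet rule can be exercised. Dropout is independent Bernoulli
zeroing at a flat rate — the simplest zero-inflation model.

Flat dropout is also the generator's main deliberate unrealism, and it
matters: at `dropout_rate = 0.2`, 20% of even the highest-expressed
mtDNA measurements vanish irrespective of expression level, which real
deep full-length data does not do. The information loss is severe for
any method operating on a linear embedding of log-normalized values:
an exact-likelihood classifier on the raw counts still separates the
planted groups almost perfectly at `mt_logfc = 1.5`, dispersion 0.3,
dropout 0.2, but the log → z-score → 2-PC route caps near 95%
assignment accuracy (ARI ≈ 0.8) at *any* baseline expression level.
Recovery tests therefore use low dropout (0–0.05) when they assert
high-fidelity recovery (ARI ≥ 0.9 at `mt_logfc = 2`), and the
acceptance suite honestly reports the flat-dropout-0.2 ARI as what it
is. Passing tests on this generator show the machinery is correct
under its stated model; they do not certify performance on data whose
zero process is expression-dependent.

`simulate_pileups()` plants variants with binomial alt counts at the
configured frequency, strand split by `strand_balance` (1.0 produces
the strand-filter negative control), read-end flags at a flat per-read
rate, and pure-reference background — no sequencing-error noise, so
any off-target call is a bug, which the recovery tests exploit
(recall ≥ 0.95 at frequency ≥ 0.03 and coverage ≥ 600, zero false
calls). `shared_alpha` variants go to alpha cells *and* both beta
subgroups, creating the candidate-inherited scenario.

`simulate_conservation_track()` builds piecewise-constant blocks with
optional beta-distributed jitter — enough structure for ratio tests,
with none of the positional autocorrelation of real phastCons tracks.

# Numerical and reproducibility choices

* All mtDNA coordinates are 1-based inclusive internally (the mpileup
  convention); bedGraph input is converted on read.
* One run seed fans out to per-stage seeds via a stable string hash of
  the stage name, so stages are independently reproducible and a rerun
  with the same config is byte-identical (asserted on output
  checksums).
* Seeded sampling is wrapped so the caller's RNG state is restored.
* Degenerate cases are errors, not silent defaults: zero-total cells
  at normalization, constant expression at PCA, tied cluster means at
  HE/LE labelling, pools smaller than the resampling size.
* Test problem sizes (a few hundred cells, mtDNA length ~1400–2000,
  repertoire iterations 200–1000 in end-to-end loops) were chosen as
  the smallest sizes at which the asserted statistical properties are
  stable; the full 1000/10,000 iteration defaults match the
  production analysis.

# Known limitations

* RNA heterogenic calls cannot be attributed to DNA heteroplasmy
  versus RNA-level processes (polymerase errors, modifications) — by
  design, as no orthogonal DNA evidence is consumed.
* Indels are skipped, not called; the D-loop is out of scope.
* The read-end filter sees only the `$` marks in pileup text; a
  distance-window variant would need per-read positions (BAM), which
  the text dialect does not carry.
* More than two expression sub-populations have no downstream
  semantics; the pipeline either finds a two-way split or flags the
  merge fallback.
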