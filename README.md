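# trioscope

Joint copy-number, methylome and transcriptome analysis of single cells.

Single-cell triple-omics protocols split one cell so that its nuclear DNA is
bisulfite-sequenced (a reduced-representation bisulfite library, RRBS) while
its cytoplasmic RNA is sequenced separately. One cell then yields three
coordinated measurements:

* a **copy-number profile** deduced from the read depth of the RRBS library,
* a **DNA methylome** from the per-CpG methylated / unmethylated read counts,
* a **transcriptome** (gene-level FPKM).

`trioscope` implements the computational pipeline for such data as a tested R
toolkit, together with a synthetic triple-omics simulator with full ground
truth so that every inference step can be validated end to end.

## What the toolkit computes

**CNV from RRBS depth.** RRBS coverage is concentrated on MspI fragments
(`C^CGG` cut sites), so raw depth cannot be read as copy number. Depth is
summed per genomic bin (10 Mb by default), library-size normalized, and
divided by a per-bin factor from a diploid bulk control; the resulting value
is anchored at 2 for diploid bins:

    value_b = 2 * (depth_b / library_total) / factor_b

Continuous values are fitted to integer copy states 0..6 by Viterbi decoding
of a per-chromosome hidden Markov model (Gaussian emissions centred on the
integer states, shared sigma, sticky transitions). Cells are clustered into
subclones by average-linkage hierarchical clustering of the normalized
profiles, and sensitivity/specificity are scored with the (1.5, 2.5) diploid
window and a ±0.5 window around aberrant copies.

**In-silico digestion and mappability.** `digest_mspi()` enumerates all
CCGG-flanked fragments of a genome; simulated end-reads from both fragment
ends are matched, after C→T bisulfite collapse of reads and both genome
strands, against the whole collapsed genome, and a fragment is kept as
*unique* only when both end-reads occur exactly once.

**CNV from expression.** Genes with mean `log2(FPKM+1) > 1.5` are normalized
to a bulk reference, smoothed with a 100-gene moving average along the genome
(50 genes up- and downstream, focal gene excluded), centred per cell, and
averaged in 10-Mb windows — an independent, dosage-based estimate of the same
copy-number structure.

**Methylome.** Single-cell CpG calls are filtered to confident binary states
(depth ≥ 3, ratio ≤ 0.1 or ≥ 0.9), summarized over promoters (TSS −1000/+500)
and gene bodies (TSS→TES minus TSS+2000 and CpG islands), correlated with
expression (`log2(FPKM+1)`), and laid out as 30-fraction metagene profiles
(5 upstream + 20 body + 5 downstream fractions).

**Heterogeneity.** 3-kb windows are ranked by cell-to-cell methylation
variance: per-cell window means weighted by reciprocal SEM, combined with the
reliability-weighted unbiased variance

    V = sum(w_i (m_i - m̄)^2) / (sum w_i - sum w_i^2 / sum w_i)

and ranked by the lower 95% chi-squared confidence bound
`(n-1) V / χ²_{0.975, n-1}`. Enrichment of the top windows in genomic
elements is tested with Fisher's exact test.

**Subpopulation differences.** CpG-island methylation is pooled within cell
subpopulations (a CGI qualifies in a cell with ≥ 5 confident CpGs and is
pooled when qualified in `max(3, ceiling(0.25 n))` cells); islands with
pooled-level difference ≥ 0.3 and Fisher p < 0.05 are called differentially
methylated (dmCGIs). Differential expression uses Wilcoxon rank-sum tests
with Benjamini-Hochberg correction, and per-cell Pearson correlations link
integer copy states to window expression and window methylation.

## Worked example

```r
library(trioscope)
library(dplyr)

# simulate a 25-cell tumor with two subclones and full ground truth
ann <- simulate_annotation(seed = 1)
sim <- simulate_population(sim_config(), ann, seed = 2)

# read-depth CNV: normalize against the diploid control, fit integer states
bins   <- count_fragments_per_bin(ann$fragments, ann$bins, unique_only = TRUE) |>
  mask_low_coverage_bins()
values <- normalize_bins(sim$bin_depth, normalization_factors(sim$control, bins))
fit    <- fit_cnv_hmm(values, bins)

tidy(fit)                      # per-cell per-bin value + integer state
inner_join(tidy(fit), sim$truth$cnv_truth, by = c("cell", "bin_id")) |>
  summarise(state_accuracy = mean(state == copy, na.rm = TRUE))
#>   state_accuracy
#> 1              1

# subclone recovery from both modalities
cl  <- cluster_cells(values, k = 2)
ari(tidy(cl)$cluster, sim$truth$cells$subpop)
#> [1] 1
wexpr <- expression_cnv(sim$expression, sim$reference, ann$genes, ann$bins)
ari(tidy(cluster_cells(wexpr, k = 2))$cluster, sim$truth$cells$subpop)
#> [1] 1

# methylation-expression coupling (negative at promoters, positive in bodies)
fcalls <- filter_cpg_calls(sim$calls)
methylation_expression_cor(
  region_methylation(fcalls, promoter_regions(ann$genes)),
  sim$expression) |> summarise(mean_r = mean(r))
#>   mean_r
#> 1 -0.332
```

`run_pipeline(run_config(), "out/")` executes the whole chain — simulation,
both CNV arms, methylome summaries, variance ranking, dmCGI and differential
expression calling — and writes result tables plus a machine-readable
`summary.json`. A small demo configuration ships in
`inst/extdata/demo_config.yaml`; a thin command-line front-end with
`digest`, `simulate` and `run` subcommands is in `inst/scripts/trioscope`.

## Package layout

* `R/genome.R` — FASTA handling, MspI digestion, mappability, genomic bins
* `R/simulate.R` — the synthetic triple-omics generator and its ground truth
* `R/cnv_rrbs.R` — depth binning, control normalization, HMM, clustering
* `R/cnv_rna.R` — expression-based relative CNV
* `R/methylome.R` — CpG filters, region methylation, metagene profiles
* `R/heterogeneity.R` — weighted variance ranking and element enrichment
* `R/subpop.R` — dmCGIs, differential expression, PCA, copy correlations
* `R/io.R` — readers/writers, run configuration, `run_pipeline()`
* `vignettes/triple-omics-methods.Rmd` — the methods vignette
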