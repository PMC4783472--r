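---
title: "Methods: joint copy-number, methylome and transcriptome analysis of single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint copy-number, methylome and transcriptome analysis of single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioscope)
```

## The measurement problem

Triple-omics single-cell protocols physically separate one cell's nucleus
(bisulfite-converted and sequenced as a reduced-representation bisulfite
library, RRBS) from its cytoplasmic RNA. The RRBS library does double duty:
its per-CpG methylated/unmethylated read counts give the methylome, and its
genome-wide read depth — after careful normalization — carries copy-number
information. The expression layer provides an independent, dosage-based view
of the same copy-number structure. This vignette explains each model in the
package, the parameters that matter, and what the bundled simulator does and
does not emulate.

## Copy number from RRBS read depth

RRBS concentrates coverage on MspI fragments (the enzyme cuts `C^CGG`), so
raw depth varies over orders of magnitude along the genome for purely
technical reasons. The package therefore:

1. sums per-position depth into genomic bins (default 10 Mb, the resolution
   at which depth is stable enough for single cells);
2. divides each cell's per-bin depth by its library total over unmasked bins;
3. divides by a per-bin *normalization factor* — the library-size-normalized
   depth of a diploid bulk control (averaged over replicates) — which absorbs
   the fragment-density and GC biases shared between cell and control;
4. multiplies by 2, anchoring a control-like cell at value 2.0 in every bin.

Two consequences are worth stating. First, the scale is *relative*: a cell
whose genome is heavily aneuploid has a library total inflated or deflated by
its aberrations, so "diploid" bins sit somewhat off 2.0 (by the factor
`2 / mean(copy)`). With realistic karyotypes this shift is modest and the
integer fit absorbs it; with a toy genome in which most of the genome is
aberrant it would not be, which is why the simulator's default karyotypes
keep the genome-wide mean copy near 2. Second, bins with unreliable coverage
must be excluded: the package masks bins whose unique-fragment count falls
below 10% of the genome-wide median (a data-driven stand-in for excluding
centromeric/telomeric windows; the threshold is exposed as `mask_frac`).

### Integer fitting

Normalized values are decoded per chromosome with a hidden Markov model:
states are integer copies 0..6, emissions are Gaussian with mean equal to the
state and a shared standard deviation `sigma` (default 0.4), the chain stays
with probability `stay_prob` (default 1 − 1e−4) and otherwise switches
uniformly, and the initial distribution is uniform. Ties are broken toward
copy 2. Both parameters are deliberately exposed: the default `stay_prob` is
very sticky, appropriate for whole-chromosome or arm-level events at 10-Mb
bins (a single-bin copy-3 excursion will be smoothed away by design); users
refining at finer bins (`refine_cnv_segments()`) should relax it. The Viterbi
implementation is validated against exhaustive path enumeration on every
instance with up to 8 bins.

### Accuracy scoring

Against known truth, specificity is the fraction of truth-diploid bins whose
*continuous* value falls in (1.5, 2.5), and sensitivity the fraction of
truth-aberrant bins within ±0.5 of the true copy — the windows used for
single-copy-X designs, where a male-like X at copy 1 must land in (0.5, 1.5).

## Copy number from expression

Dosage couples expression to copy number. The package follows the standard
moving-average approach: select genes with mean `log2(FPKM+1) > 1.5` across
cells; normalize to a bulk diploid reference
(`log2(FPKM_cell+1) − log2(FPKM_ref+1)`); average the 100 genes around each
gene (50 up- and downstream in genomic order, focal gene excluded, truncated
at chromosome ends); centre per cell; average per 10-Mb window. The moving
average is computed on log-scale reference-relative values rather than raw
FPKM: the centering step and cross-cell comparability only make sense on
relative values, and a raw-FPKM mode is available in `expression_cnv()` for
users who want the literal alternative.

The order of operations is fixed as select → relative → moving average →
centre → window-average → cluster.

## Methylome summaries

Single-cell bisulfite calls are only trustworthy when deeply covered and
nearly homogeneous, so the per-CpG filter keeps sites with depth ≥ 3 and
ratio ≤ 0.1 or ≥ 0.9, binarized to 0/1. (The depth cut-off is read as "at
least 3"; bulk data skip binarization via `binarize = FALSE` and work with
raw ratios.) Region levels are unweighted means over detected sites and are
*undefined* — not zero — below the minimum site count: more than five CpGs
for promoter/gene-body levels (`min_cpgs = 6`), at least five for CpG-island
qualification (`min_cpgs = 5`). Undefined values propagate as missing
throughout; 0 is a valid methylation level and never a placeholder.

Regions are strand-aware: promoters span 1000 bp upstream to 500 bp
downstream of the TSS; gene bodies run TSS→TES minus the first 2000 bp
downstream of the TSS and minus CpG islands. Metagene profiles divide each
body into 20 equal fractions and each 15-kb flank into 5; each detected CpG
of a gene belongs to exactly one of the 30 fractions (a partition, tested as
such), and the profile averages within genes first, then across genes.
Methylation-expression correlations are plain Pearson on
`log2(FPKM+1)` (FPKM below 0.001 reset to 0.001); genes are not pre-binned
by expression rank, though a ranked variant is exposed since the field
sometimes arranges genes by expression before correlating.

Multi-transcript genes are treated as one record per annotation row; no
transcript collapsing is attempted.

## Cell-to-cell methylation variance

For 3-kb windows, the per-cell mean level and its SEM (population SD of the
per-CpG levels divided by √n; floored at `sem_floor = 0.01` so that
homogeneous windows do not get infinite weight) feed a reliability-weighted
variance with weights 1/SEM:

$$V = \frac{\sum_i w_i (m_i - \bar m)^2}{\sum_i w_i - \sum_i w_i^2 / \sum_i w_i},$$

which reduces to the ordinary sample variance under equal weights (tested to
1e-12). Windows are ranked by the lower 95% chi-squared confidence bound
$(n-1)V/\chi^2_{0.975,\,n-1}$, which penalizes windows observed in few
cells. The exact SEM definition and variance denominator are choices of this
package (the field's descriptions leave them open); both are configurable.
Element enrichment of the top windows uses a ≥1-bp overlap rule and
two-sided Fisher tests with Benjamini-Hochberg correction across elements.

## Subpopulation comparisons

dmCGI calling pools binarized CpG counts within subpopulations. The
qualified-cell minimum generalizes the absolute counts used in small designs
as `max(3, ceiling(0.25 n))` — which reproduces 3-of-7 and 5-of-18 exactly —
and a CGI is emitted as differentially methylated when the two-sided Fisher
test on the pooled 2×2 table gives p < 0.05 *and* the absolute level
difference is at least 0.3 (the threshold is inclusive, ≥ 0.3). Differential
expression deliberately uses the minimal-assumption Wilcoxon rank-sum test
on `log2(FPKM+1)` with BH correction (constant genes get p = 1); no claim of
equivalence with any particular published gene list is made. PCA operates on
gene-centred `log2(FPKM+1)` without unit-variance scaling, with component
signs fixed by making the largest-magnitude loading positive.

## The simulator: what it emulates, and what it does not

`simulate_annotation()` + `simulate_population()` generate a toy genome and a
two-subpopulation single-cell dataset with complete ground truth. The default
study conditions were fixed once and are used by the acceptance checks:

* **Genome**: 10 chromosomes × 40 Mb, 10-Mb bins, ~1200 uniquely mappable
  fragments per bin placed preferentially at promoters/CGIs and gene bodies
  (RRBS is CpG-biased), 25 genes per bin, 70% of promoters carrying a CGI.
  A real genome has ~22 autosomes; 10 toy chromosomes keep enough
  independent noise components for stable clustering while staying fast.
* **Karyotypes**: subpopulations of 7 and 18 cells sharing a whole-chromosome
  gain (chr1, copy 3), with private gains (chr2, chr4) and a private loss
  (chr5) in subpopulation I and private losses (chr3, chr6) in II. About half
  the genome differs between subclones, matching heavily rearranged tumors,
  and the genome-wide mean copy stays near 2 so the relative depth scale
  remains anchored. Events are whole chromosomes because arm/chromosome-level
  aneuploidy is what 10-Mb binning resolves.
* **RRBS noise**: each unique fragment is captured independently with
  probability `capture_prob × copy/2` (default 0.5 at diploid); per-CpG depth
  is Poisson(6) (negative-binomial over-dispersion is a config knob, default
  off, kept off so the acceptance oracles stay analytic); CpGs drop out with
  probability 0.1.
* **Methylation**: gene-level promoter and body means sit on a logit scale
  (promoter intercept −1.7 — the TSS valley — body intercept 1.1) with
  couplings to standardized log-expression of −1.2 (promoter, repressive) and
  +0.8 (body, activating). Per cell and CpG, a binary allele state is drawn
  with probability equal to the regional mean and reads report that state up
  to a 1% error. This Bernoulli layer is the default because single-cell
  CpGs are bimodal (two alleles): a literal Binomial(depth, regional-mean)
  model — also available as `meth_model = "binomial"` — produces intermediate
  ratios that the confident-call filter removes, which would flatten region
  levels and erase the couplings the filter is designed to preserve. A
  fraction (15%) of CGIs is bimodal *across* cells (each cell toggles between
  levels 0.1 and 0.9), planting the cell-to-cell variance structure that the
  heterogeneity ranking must recover. Methylation is independent of copy
  number by default (`meth_copy_coupling = 0`), matching the biology the
  toolkit is designed to test.
* **Expression**: baseline FPKM is log-normal (meanlog log 8, sdlog 1.2);
  per cell, FPKM is log-normal around `baseline × copy/2` with sdlog 0.5 and
  drops to zero with probability 0.15.

Not emulated: raw reads and alignment, bisulfite conversion errors beyond
the 1% state-error, allele-specific methylation or expression, fragment size
selection, GC-bias beyond what the control-ratio normalization absorbs
(depth and fragment density are simulated as proportional, so a separate GC
covariate would have nothing to fit), and non-CpG methylation. Passing the
recovery checks on these simulations therefore demonstrates the correctness
of the *inference machinery* under a known generative model — not
performance on any particular real dataset.

## Numerical choices and degenerate inputs

* Coordinates: BED-like tables are 0-based half-open; CpG coverage tables use
  1-based cytosine positions (the common methylation-caller convention).
* MspI cut convention: `C^CGG`, fragment coordinates cut-to-cut; fragments
  before the first and after the last site of a chromosome are not emitted.
  Mappability is exact-match in C→T-collapsed space — stricter than a real
  bisulfite aligner's mismatch model, and documented as such. No fragment
  size selection is applied by default (an optional length filter can be
  imposed by the caller); genome-scale unique-fragment counts from real
  references are out of scope.
* Bin assignment is by fragment start; a fragment belongs to exactly one bin.
* Viterbi ties break toward copy 2, then the smaller state, making decoding
  deterministic.
* Clustering of identical cells returns a single flat cluster rather than an
  arbitrary cut.
* Correlations are undefined (NA with a warning) below 3 paired observations
  or at zero variance; pairwise cell correlations need ≥ 10 co-detected
  sites.
* `run_pipeline()` writes all outputs with fixed ordering and rounding, so
  reruns with the same configuration and seed are byte-identical.

## Problem sizes used by the validation suite

The test suite and `scripts/acceptance.R` run on deliberately scaled-down
instances chosen to exercise every code path with comfortable statistical
margins: 500 (tests) / 200 (script) random HMM instances of ≤ 8 bins against
exhaustive enumeration; 20-25-cell populations at the default ~1200
fragments/bin for copy-state and subclone recovery; 200-replicate (tests) /
100-replicate (script) null simulations for dmCGI calibration; 10 replicate
populations for the copy-methylation independence check (a fixed methylation
landscape has an O(1/√n_bins) chance correlation with any copy profile that
is shared across cells, so independence is assessed on the grand mean across
independently generated landscapes); and 500-gene populations for the
coupling-sign checks. The expression-side concordance check runs with
expression dropout disabled so that its expectation has a closed form under
the log-normal dosage model.
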