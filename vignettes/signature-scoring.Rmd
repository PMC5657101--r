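---
title: "Scoring molecular signatures across individual samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring molecular signatures across individual samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(savant)
```

## The problem

A molecular signature is a collection of genes characteristic of a cell
type, tissue, disease, or perturbation. Enrichment tools typically reduce an
entire experiment to one filtered gene list, discarding the per-sample
variation that makes patient subgrouping possible. This package takes the
opposite view: it evaluates each signature in *each individual sample* of a
user-supplied expression matrix, producing a signature-sample matrix that
can be annotated with statistical evidence and displayed as a clustered
heatmap.

## Signature generation: proportional medians

Given a normalized multi-sample compendium (one data series at a time), the
proportional median (PM) of gene $g$ in condition $c$ is

$$\mathrm{PM}_{g,c} = \frac{x_{g,c}}{\mathrm{median}_{c'}\, x_{g,c'}},$$

the gene's intensity divided by its median across all conditions of the same
series. A gene expressed at a similar level everywhere has PM near 1 in
every condition; a gene strongly over-expressed in one condition has a large
PM there. A ranked signature for condition $c$ is the list of genes sorted
by descending $\mathrm{PM}_{g,c}$, truncated to the top $k$ (default 50; any
size is accepted by the library, and the command line restricts itself to
the conventional menu 10, 25, 50, 100, 250, 500, 1000).

Preprocessing before PM computation follows standard compendium practice:
biological replicates are averaged per probe
(`average_replicates()`), and a gene measured by several probes is
represented by the probe with the highest mean intensity across all samples
(`collapse_probes()`). Whether probes are collapsed to genes before or after
PM computation is not uniquely determined by that practice; both orders are
exposed in `generate_signatures()` via `collapse_first`, with
collapse-first as the default.

Numerical conventions, chosen where more than one convention exists:

* medians over an even number of conditions use the midpoint of the two
  middle values (R's default);
* gene rows whose median is zero are dropped (with a message) rather than
  assigned infinite PM — an essentially absent probe cannot anchor a ratio;
* PM ties at the truncation boundary are broken by gene-id lexicographic
  order, so a regenerated signature is bit-identical.

`compute_pm()` is invariant to per-gene positive rescaling (the ratio
cancels the scale) and requires at least two conditions, since a median over
one sample would force every PM to 1.

## The signature-sample matrix

`score_signatures()` computes, for every signature $s$ and sample $j$,

$$S_{s,j} = \frac{1}{|G_s|} \sum_{g \in G_s} x_{g,j}$$

where $G_s$ is the set of signature genes *present in the matrix* (sums
instead of means with `mode = "sum"`). Ranked signatures are truncated to
the top $k$ genes first; unranked MSigDB-style sets are used whole. Genes
absent from the matrix are skipped rather than imputed as zero — platform
coverage should not masquerade as biology — and the per-signature count of
genes actually used is recorded, with a `min_genes` filter for users who
want to drop sparsely covered signatures.

Optional expression transforms run before scoring, in a fixed order: log
then rank. The log transform is $\log_2(x+1)$ (base 2 is the transcriptomics
convention; the pseudocount guards zeros). Ranks are per sample column,
ascending, ties averaged — high expression must map to high rank so that
signatures of over-expressed genes score high.

Post-processing of the score matrix applies, in order:

1. `scale_sqrt`: multiply each row by $\sqrt{|G_s|}$. A mean of $m$ roughly
   independent values has standard error $\propto 1/\sqrt{m}$; multiplying
   by $\sqrt{m}$ makes scores comparable across signature sizes.
2. `diff_from_mean`: subtract each signature row's mean across samples.
3. `zscore`: subtract the grand mean of the whole matrix and divide by its
   grand standard deviation (population convention, denominator $=$ cell
   count). `diff_from_mean` and `zscore` rescale incompatibly and are
   mutually exclusive.
4. `min_value`: drop rows whose maximum falls below the threshold (a
   display filter, read per signature).

One ambiguity was resolved deliberately: difference-from-mean is implemented
on the *score* matrix (per signature), the form used when contrasting
patient groups; a per-gene variant on the expression matrix is not
implemented.

## Empirical p-values

The null model asks: would a randomly chosen gene set of the same size score
this high in this sample? For each present-gene count $m$, `n_perm` gene
sets of size $m$ are drawn uniformly without replacement from the matrix's
gene universe and scored with the same statistic; the per-cell p-value is

$$p_{s,j} = \frac{1 + \#\{\text{null} \ge \text{observed}\}}{n_\mathrm{perm} + 1},$$

one-sided in the upper tail (signatures encode over-expression), with the
add-one guard so that finite sampling never reports $p = 0$. Draws are
stratified and cached by $m$: two signatures with the same present-gene
count share null sets, which matches the null's definition and cuts cost
roughly tenfold; each null set's member genes are scored in every sample.
The default is 10,000 draws. A single seeded random stream, consumed with
signatures in output order, makes the p-value matrix bit-reproducible.

Gene-label resampling — rather than shuffling matrix cells — preserves each
sample's expression distribution exactly, which is the property the score
must be judged against. P-values are computed per signature-sample cell.

## Group ANOVA

When the input matrix carries a `SAVANT_GROUP` row (integer group codes, one
per sample), a classical one-way fixed-effects ANOVA runs automatically per
signature across the groups, via `stats::oneway.test(var.equal = TRUE)`:
$F = \frac{\mathrm{SS_{between}}/(g-1)}{\mathrm{SS_{within}}/(n-g)}$ on
$(g-1, n-g)$ degrees of freedom. Constant rows are reported as $F = 0$,
$p = 1$; perfect separation is clamped to the smallest representable
p-value. Star labels are attached per signature: `***` for $p \le 10^{-4}$,
`**` for $p \le 10^{-3}$, `*` for $p \le 10^{-2}$. `filter_by_pvalue()`
keeps signatures with $p$ strictly below a chosen `alpha`
(the group-discrimination workflow uses $10^{-4}$). No multiple-testing
correction is applied across signatures; the filter operates on raw
p-values by design.

## Clustering and rendering

Rows and/or columns of the final (filtered) score matrix can be clustered
agglomeratively with Euclidean distance or Pearson distance ($1 - r$), under
single, complete (default), average, or Ward linkage. Ward is allowed only
with Euclidean distances, where its objective is defined. Leaf order is the
standard `hclust` dendrogram traversal. Dendrograms serialize to Newick with
merge heights as branch lengths. `render_heatmap()` writes a static image —
diverging palette centered at 0 whenever the matrix contains negative values
(e.g. after z-scoring), sequential otherwise — plus a tab-delimited
companion table of the exact reordered values, so no information is trapped
in the picture. Clustering runs after the min-value and p-value filters.

## The synthetic-data generator

`generate_dataset()` draws background expression i.i.d. from
$2^{\mathcal{N}(6,\,1)}$ — log-normal with location 6 and scale 1 on the
log2 scale, mimicking normalized array intensities — and multiplies disjoint
spiked gene sets by a fold change in the samples of their target group.
`generate_compendium()` builds the analogous object for the
signature-generation path: disjoint marker sets upregulated in each
condition's replicates. Multiplicative spikes on a log-normal background
mirror the ratio semantics of proportional medians; an additive model would
break PM's scale-invariance. Every generator requires an explicit seed and
regenerates bit-identically from it.

What the generator does *not* emulate: probe saturation, batch effects,
gene-gene correlation, heavy-tailed platform noise, and library-size
artifacts of RNA-seq counts. Tests passing on these fixtures therefore
demonstrate correctness of the computations and calibration of the null
under idealized noise, not robustness to real-platform pathology.

Validation problem sizes, chosen to represent a small but non-trivial
experiment: scoring-recovery datasets use 2,000 genes, two groups of 10
samples, one 50-gene spike at fold 4; compendium recovery uses 5 conditions
with 4 replicates each (a typical curated series depth), 50 markers per
condition at fold 8 over a 2,000-gene pool; the null-calibration check uses
200 signature-sample cells at 1,000 permutations.

## Known limitations

* Signature scores are relative summaries, not quantitative cell-fraction
  estimates; deconvolution is out of scope.
* Only over-expression is tested; depletion (lower tail) is not.
* Input matrices must be complete — missing values are rejected rather than
  imputed.
* Multi-series compendia must be split by the caller before PM computation,
  since the PM denominator is defined within one series.
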