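---
title: "Methods: simulated bisulfite methylome comparison in a TE-rich genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated bisulfite methylome comparison in a TE-rich genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# Scope

methylTE implements a complete whole-genome bisulfite sequencing (WGBS)
comparison between two genotypes — a wild type and a mutant with globally
reduced DNA methylation, the situation typical of knockouts of
chromatin-remodeler genes such as *DDM1* in plants — together with a
synthetic-data module that generates every input with known ground truth.
This vignette records the statistical model behind the generator, the
numerical conventions of each analysis stage, and the decisions taken where
the underlying methods literature leaves choices open.

# The generative model

## Genome and annotations

`simulate_genome()` draws `n_chromosomes` chromosomes of `chrom_length` bp
(defaults: 2 x 250 kb, a deliberate desk-scale choice — all pipeline
operations are linear in genome size and the defaults keep a full run under
a minute while still yielding ~4,000 50-bp TE windows, enough for stable
medians). Each chromosome is partitioned into alternating heterochromatic
and euchromatic blocks; heterochromatic blocks carry higher GC (0.55 vs
0.35) and higher H3/H3K9me2 proxy tracks, mimicking the
pericentromere-versus-arm contrast of plant genomes.

Transposable elements occupy `te_density` (default 0.4) of the sequence,
with `frac_hetero_te` (default 0.7) of them placed in heterochromatic
blocks; genes are placed only in euchromatin. Placement is
first-fit-decreasing with stick-breaking gaps; infeasible packings (density
too high for the block structure) raise an error rather than silently
overlapping features. TE lengths are log-normal (median 1.5 kb, clamped to
0.3–6 kb). 30% of TEs are LTR-class, with terminal repeats annotated as 15%
of the element length per side — both proportions are modeling choices, not
measured values. A configurable subset of LTR-class TEs
(`n_upregulated_te`, default 35) is flagged "predisposed": lowly methylated
in the wild type and transcriptionally upregulated in the mutant.

## Ground-truth methylomes

Every cytosine on both strands receives a true methylation probability
`p`. Within each 50-bp window, each (compartment, context) group draws one
level from a Beta distribution with mean `mu` and concentration
`beta_concentration` (default 20), then each cytosine adds N(0, 0.03)
jitter, clipped to [0, 1]. Means default to:

* heterochromatic TEs: `wt_levels` = CG 0.8, CHG 0.8, CHH 0.3;
* euchromatic TEs: CG/CHG from `wt_levels`, CHH = `eu_chh_level` (0.08);
* gene bodies: CG only, `gene_cg_level` (0.05);
* intergenic background: 0.01;
* predisposed-TE positions: 0.1.

Gene-body and intergenic levels are open-question choices: studies of this
design usually report TE methylation only, so the low defaults exist to
create TE/gene contrast, not to match a measured value.

The mutant methylome applies the per-context multiplicative reduction
`mutant_reduction` (default CG 0.75, CHG 0.75, CHH 0.25) to every cytosine:
`p_mut = p * (1 - r[context])`. On top of this, euchromatic-TE CHH
cytosines in windows whose wild-type CHH mean is below `chh_low_threshold`
(0.15) gain `chh_hyper_gain` (0.1), clipped to [0, 1]. This reproduces the
CHH "redistribution" phenotype — hyper-methylation confined to lowly
methylated euchromatic TE sequence while heterochromatic CHH drops — while
keeping the `chh_hyper_gain = 0` case an exact multiplicative reduction, so
parameter-recovery tests have a well-defined target.

## Bisulfite reads

`simulate_bisulfite_reads()` emits directional paired-end reads. Fragments
are exactly `2 * read_length` bp, so mates never overlap and no
double-counting correction is exercised by default (the pileup still
implements mate-overlap deduplication for constructed inputs). The pair
count is `round(coverage * genome_length / (2 * read_length))`; because
each fragment is assigned to one template strand uniformly, the expected
per-strand depth at a cytosine is `coverage / 2`. Chemistry follows two
Bernoulli parameters: a methylated C survives as C with probability
`meth_protection`, an unmethylated C converts to T with probability
`conversion_rate` (both default 1, i.e. perfect chemistry, so oracle tests
are exact); `seq_error` (default 0) substitutes random bases after
conversion. All randomness derives from one seed; generator stages use
fixed offsets (+1000 methylomes, +2000/+3000 reads, +4000 expression) so
stages can be re-run independently yet reproducibly.

## Expression counts

`simulate_expression_counts()` draws negative-binomial counts (dispersion
`nb_dispersion` = 0.1, i.e. size 10) for all genes and TEs, `n_reps` = 3
replicates per genotype. Genes have log-normal base means around 80, TEs
around 1 (silenced), predisposed TEs around 15; predisposed TEs are
multiplied by `de_fold` (default 8) in the mutant and listed in the
returned truth table.

# Analysis conventions

## Three-letter alignment

Reads are aligned ungapped in "three-letter" space: C→T-converted read
against the C→T genome for a plus-strand template and G→A against the G→A
genome for a minus-strand template, with mate-2 orientation handled by
reverse complementing. The seed-and-extend search uses three seeds at
thirds of the read; with the mismatch budget capped at 2, at least one seed
is exact for any valid placement (pigeonhole), so the search is exhaustive
— this is what makes the brute-force equivalence tests meaningful. Reads
with more than 2 mismatches or more than 10 equally good placements are
discarded; among up to 10 ties one placement is drawn uniformly with a
seeded RNG and the tie count is recorded as `multiplicity`.

## Methylation calling and windows

Pileup counts, per template-strand cytosine, reads showing C (`n_C`) versus
T (`n_T`); other bases are ignored as errors. Context (CG/CHG/CHH, H = A,
C or T) is taken from the two downstream bases on the cytosine's own
strand; positions within two bases of a chromosome end or adjacent to N
have no context and are excluded. Windowed methylation is the
count-weighted fraction `sum(n_C) / sum(n_C + n_T)` over 50-bp tiles
(`step = width` by default; sliding windows are supported). A
window-context needs `min_calls` = 4 informative calls for a defined
fraction — a pragmatic floor that suppresses single-read windows without
discarding much of a 30x dataset.

## Differential methylation

The headline statistic is the signed percent change
`100 * (m_b - m_a) / max(m_a, m_b)`: symmetric in scale, bounded in
[-100, 100], and defined as 0 for the degenerate 0/0 case (no evidence, no
change). TE-level summaries use windows overlapping the TE set by at least
50% of their width; the same >= 50% rule defines "TE windows" for
stratified analyses. Matched CG/CHG comparisons keep windows with equal
(and nonzero) covered CG and CHG site counts in both samples and a maximum
methylation above `min_meth` = 0.5, removing the site-density confound
before contrasting the two symmetric contexts. Quantile stratification
ranks TE windows by an attribute (typically wild-type CHH level) into five
equal-size groups, ties broken by coordinate for determinism.

## Meta-profiles

`te_metaprofile()` anchors TEs at their strandwise 5' or 3' end and bins
signed offsets (default 100 bp; 50 bp gives finer figure-style profiles —
the default favors per-bin evidence over resolution). Each element
contributes only up to its own boundary, up to the nearest other annotated
feature, and at most `max_offset` = 2000 bp, so flanks are never
contaminated by neighboring elements. Bins are count-weighted pooled over
elements.

## Differential expression

Counts are filtered at a total (all replicates) below 10, converted to
log2(CPM + 0.5), and compared with a per-feature two-sided Welch t-test;
"up" requires fold-change >= 2 and p < 0.05. The deliberately simple test
is part of the package definition — no variance moderation is applied,
which at n = 3 costs sensitivity relative to moderated models (measured
~0.84 at an 8-fold change with dispersion 0.1) but keeps the procedure
free of modeling assumptions and exactly reproducible. Multimapping read
assignment for the count matrix keeps reads with fewer than 100 candidate
loci, choosing one locus uniformly at random with a seeded RNG; a read
maps to the feature covering at least half of it, larger overlap winning
and ties going to the TE.

# Limitations

* Alignment is ungapped; indels, clipped alignments and PCR duplicates are
  out of scope.
* The genome is i.i.d. random sequence within blocks: no real repeat
  families, so multimapping is much rarer than in real TE-rich genomes.
* Perfect chemistry defaults mean conversion-failure correction is never
  exercised unless `conversion_rate < 1` is set explicitly.
* The Welch t-test at n = 3 is underpowered compared to moderated models;
  users wanting power should raise `n_reps` rather than expect the test to
  borrow strength across features.
* Beta-plus-jitter methylation has no spatial autocorrelation beyond the
  50-bp window, so segmentation methods would look artificially good on
  these data.

# Reproducing a full run

```{r}
library(methylTE)
params <- sim_params(seed = 1)
report <- run_pipeline(run_config(params, outdir = "methylte_run"))
str(report$context_reduction)
```

The run report (`report.json`) carries per-context TE methylation
reductions, matched-window medians, CHH quantile medians, DE counts, and
an MD5 manifest of all written files; two runs with the same seed produce
identical reports.
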