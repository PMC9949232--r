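---
title: "Methods: peak calling, 5hmrC reduction and Tet target integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak calling, 5hmrC reduction and Tet target integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitet)
```

# The problem

Tet dioxygenases act twice on a gene: they bind its promoter DNA, and they
are required for the 5-hydroxymethylcytosine (5hmrC) modification of its
mRNA. A gene is called a *Tet target* when three independent lines of
evidence converge: (1) a reproducible Tet ChIP peak, preferentially at the
promoter and co-localizing with the active-promoter mark H3K4me3; (2) at
least one 5hmrC peak on its transcript whose signal drops by at least
1.4-fold when Tet is removed; and (3) an mRNA level that does not change
appreciably without Tet — the modification affects translation, not
steady-state abundance, so expression-changed genes are treated as
secondary effects.

`epitet` implements this integration end-to-end, together with a seeded
synthetic-data generator, so every stage can be validated against planted
ground truth on a desk-scale genome.

# Peak calling

## Model

Per-base IP depth is compared against an expected background with a
Poisson upper tail, `P(X >= k)` for `X ~ Poisson(lambda)`
(`poisson_enrichment_pvalue()`). For DNA (ChIP) calling, `lambda` at a
base is the maximum of the genome-wide input rate and local input rates in
1 kb and 10 kb centred windows — the MACS-style "local lambda" that absorbs
regional biases. Candidate bases at p < 1e-2 are merged across gaps
shorter than the 147 bp fragment-extension footprint; each region reports
its leftmost depth-argmax as the summit, the summit tail probability as
its p-value, summit IP depth over summit background as fold enrichment,
and the region's IP coverage integral divided by the read length as its
supporting reads.

Two dialects mirror the two tissue stages of the study design:

* **embryo** — candidates are emitted and then filtered by the strict
  selection `p < 1e-5`, `fold enrichment > 10`, `reads > 50`
  (`filter_criteria()`; all three bounds strict, and the read count is the
  whole-peak count, one of the two readings of the rule — documented and
  configurable). The threshold `1e-5` reads the "10e-5" convention as
  10^-5, the MACS-conventional value; it is configurable for anyone who
  prefers the literal 10^-4.
* **larva** — a Benjamini–Hochberg q-value cutoff (q < 0.05) and a resize
  of every peak to 100 bp on both sides of its summit.

## Numerical choices worth knowing about

**Input scaling.** The input track must be scaled to the IP before
background estimation. Scaling by total library size is biased whenever a
non-negligible share of the IP library sits in true peaks — the background
estimate inflates by exactly that share and every fold enrichment deflates
correspondingly. At desk scale (200 peaks on 1 Mb) that share is ~40%, so
`call_peaks()` scales by the ratio of median per-base depths instead,
falling back to the library-size ratio when coverage is too sparse for a
meaningful median. On real data with a small signal fraction the two
estimators agree.

**Larva q-values.** The BH adjustment is computed over the per-base
p-values of the whole genome, and each peak looks up the q-value at its
summit. Adjusting only the candidate-peak p-values would be badly
anti-conservative: candidate summits are selected maxima, so their
p-values are small by construction and essentially every noise candidate
would survive q < 0.05.

**Ties.** Every argmax (summits, nearest matches) breaks ties toward the
leftmost coordinate, which keeps runs bitwise reproducible.

## Replicate reproducibility and saturation

A peak is reproducible between replicates when the two summits lie within
a window `w`, read as the *maximum summit-to-summit distance* (the
alternative reading, total window width, only rescales the ladder; the
saturation property is invariant to the choice). `saturation_analysis()`
counts reproducible peaks over the 50–300 bp ladder and selects the
smallest window within 2% (configurable) of the count at the largest
window; with the generator's 40 bp replicate summit jitter the curve
saturates in the 150–250 bp range, consistent with selecting 250 bp for
downstream consensus. `multi_replicate_consensus()` keeps first-replicate
peaks reproducible against every other replicate; all-vs-first is the
default (configurable window), with the first replicate's summit as the
consensus summit.

# Genomic context

`feature_index()` derives seven classes from the annotation. The promoter
window is TSS −1000..+100 bp (strand-oriented; the window is not dictated
by anything in the data, so it is a documented, configurable HOMER-like
default) and the TTS window is ±100 bp. Peaks are classed by *summit*
with priority promoter-TSS > TTS > 5'UTR > 3'UTR > exon > intron >
intergenic; summit annotation avoids the multi-class ambiguity of wide
intervals. Co-localization with H3K4me3 is interval overlap of at least
1 bp, reported for all peaks and for the promoter-annotated subset.

`metagene_profile()` normalizes coverage to per-million library scale,
bins 5 kb flanks at 100 bp, scales each gene body to 100 bins by
mean-within-bin (bodies shorter than the bin count are interpolated, not
dropped), and reverses minus-strand rows so bins always run 5'→3'.

# The hMeRIP (RNA) side

## Calling 5hmrC peaks

RNA peaks use the same Poisson machinery restricted to transcript
footprints, but the background is each transcript's own scaled input rate
rather than genomic local windows. This is the expression control: a
highly expressed transcript has proportionally high input coverage and
must beat *its own* background. Genomic 10 kb windows would leak a strong
neighbour's coverage into a weak transcript's background and mask its
peaks, so they are disabled for this dialect. Peaks are selected at
p < 1e-5 only (no fold-enrichment or read filter, matching the RNA-side
selection rule) and assigned to their host transcript by summit; summits
outside any transcript are excluded and reported.

## Element distributions

Peak summits are classed into 5'UTR / CDS / intron / 3'UTR by exact CDS
boundaries; introns are the non-exonic transcript span; a CDS-less
transcript splits its exonic bases at the midpoint into 5' and 3' halves
(documented convention; the generator always emits a CDS). The *predicted*
distribution under random placement is available analytically
(`length_proportional`) and by seeded Monte-Carlo placement
(`monte_carlo_uniform`, the default, with the analytic model as
cross-check — the two agree within Monte-Carlo error, tested at
n = 1e5 within 1%), with a chi-square goodness-of-fit readout.

## The 1.4-fold reduction classifier

A peak is *reduced* when the normalized wild-type signal is at least
1.4-fold the Tet-null signal. The threshold is inclusive ("at least
1.4-fold"), and configurable. Signal is the mean IP coverage over the
peak interval averaged across replicates, normalized to a per-million
*background-equivalent* scale: the coverage vector is split into
contiguous covered runs and each run contributes its median depth times
its length. A plain library-total denominator is not genotype-invariant —
when Tet loss genuinely removes peak mass, total-count normalization
inflates every Tet-null signal by the lost share (~7% at generator
defaults) and pushes true 1.5-fold reductions below the 1.4 threshold;
run-median normalization estimates the background scale, which is what
the two genotypes actually share. The Tet-null signal is floored at 0.5
per million before division. The classifier is scale-invariant by
construction.

The per-peak p-value is a two-sample moderated-t-style test on
replicate-level log2 signals with per-peak variances shrunk toward their
global mean (prior df 4, configurable); the decision rule is the fold
threshold — the p-value is reported as supporting evidence, matching the
role it plays in the original decision rule. A transcript is flagged
reduced when any of its peaks is, and per-element reduction fractions
(the CDS/intron versus UTR readout) are attached to the summary.

# Motif enrichment stand-in

Full PWM discovery is out of scope; `kmer_enrichment()` recovers the
planted consensus by exhaustive k-mer counting (k = 6 default) against a
dinucleotide-preserving shuffle background (Altschul–Erickson Eulerian
walk; dinucleotide counts are preserved exactly and asserted in tests).
DNA mode collapses reverse complements; RNA mode is strand-specific
because hMeRIP motifs live on the transcript. The ranking statistic is
`z = (fg − shuffle mean) / shuffle sd`. The p-value is the larger of a
Poisson tail on the shuffle mean and a continuity-corrected t tail with
`n_shuffles − 1` degrees of freedom: most of the 4^k k-mers have small,
discrete counts for which a normal tail is anti-conservative, while the t
component guards against overdispersion and sd-estimation noise. With
this combination the null family-wise BH discovery rate sits at the
nominal level (measured over seeded null runs in the test suite).

# Expression integration

`normalize_counts()` scales every sample to the mean library size (the
normalization target is a free choice; the mean keeps counts on their
original scale). `differential_expression()` is a deliberately minimal
negative-binomial stage: pooled method-of-moments dispersion per gene,
shrunk toward the across-gene median dispersion (prior weight 2), a Wald
test on log2 fold change with a delta-method standard error, BH
adjustment, and the decision rule |fold change| ≥ 2 and adjusted
p < 0.05. The package implements this directly rather than wrapping a DE
package because the decision rule, not the estimator, is the contract;
an independent DESeq2 fit is used as a cross-check in the test suite and
agrees on log2 fold changes (r > 0.95) and on strong planted calls.

`build_gene_sets()` and `integration_report()` assemble the final sets —
bound, promoter-bound, modified, reduced, up/down/unchanged — report all
pairwise intersection fractions plus optional cross-stage overlaps, and
emit the target list `bound ∩ modified ∩ reduced ∩ unchanged` with
per-gene evidence columns. "Unchanged" means failing the DE rule, the
operational version of "negligible expression change". Both
transcript-level and gene-level denominators are available from the
summary tables since one transcript per gene is simulated; on real
annotation the mapping is provided by the gene map argument.

# The synthetic-data generator

`simulate_run()` emulates, at desk scale, the statistical structure the
analysis assumes:

* **Genome/annotation** — non-overlapping genes on both strands with
  exons, introns, UTRs and a CDS; uniform random sequence except planted
  motifs; lognormal expression floored at 0.2 so every transcript is
  detectably expressed.
* **ChIP** — Poisson background (depth 10/bp), triangular peak kernel of
  half-width 147 bp (the fragment-extension convention), planted fold
  enrichments 10–20, 60% of peaks in promoter windows, per-replicate
  summit jitter sd 40 bp, H3K4me3 peaks co-occurring with probability 0.4
  plus unrelated promoter H3K4me3 peaks. The truth records the realized
  per-replicate summit of every peak, so recovery is scored against what
  was actually planted in a replicate rather than the pre-jitter
  position.
* **hMeRIP** — coverage over whole transcript footprints (pre-mRNA style,
  so one caller serves both assays and splice-awareness is unnecessary);
  peaks placed by element weights (default 0.1/0.5/0.3/0.1 over
  5'UTR/CDS/intron/3'UTR); in the Tet-null genotype 45% of modified
  transcripts have one peak whose IP coverage over the footprint is
  divided by 1.5. Dividing the whole footprint coverage (baseline
  included) rather than only the additive enrichment keeps the
  interval-mean wild-type/Tet-null signal ratio equal to the reduction
  factor, which is what the boundary definition of a reduced peak
  (wt/ko = 1.4 exactly ⇒ reduced) presumes.
* **Counts** — negative binomial, dispersion 0.05, 6% DE genes at 4-fold
  (80% up), three replicates per condition.

Everything is driven by one master seed forked per stage, so adding or
reordering stages cannot silently change another stage's stream, and all
written outputs are byte-identical given the seed.

## What the generator does not emulate

Read-level artifacts (duplicates, mapping ambiguity, GC bias), splice
junctions, isoform mixtures, antibody off-target pulldown, batch effects
and overdispersed coverage noise are all absent. Passing tests therefore
demonstrate that the *algorithms* are correct and calibrated under the
stated statistical model, not that a real library would yield the same
operating characteristics; on real data the filters' strictness and the
robust normalizations are expected to matter more, not less.

# Problem sizes and defaults

The test suite and the acceptance script run, on one CPU: ChIP recovery
on a 1 Mb genome with 200 planted peaks (two replicates); a matching null
genome; the reduction classifier on 1000 modified transcripts over
3.6 Mb; DE on 2000 genes at 3 vs 3; motif enrichment on 300 sequences of
101 bp with 50 shuffle iterations; and the bundled demo pipeline (200 kb,
40 genes) end-to-end twice to assert byte-identical outputs. These sizes
were chosen as the smallest at which the binomial error bars of the
planted parameters are meaningfully tight.

# Known limitations

* The Poisson noise model has no overdispersion parameter for coverage;
  real IP libraries are overdispersed, which would widen the null beyond
  the nominal Poisson tail.
* The reduction classifier's background-equivalent normalization assumes
  enriched bases are a minority of each covered run.
* One transcript per gene; isoform-level assignment is out of scope.
* The moderated-t p-value for reduced peaks is undefined with a single
  replicate per genotype (the fold-change rule still applies).
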