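---
title: "Methods: ceRNA network inference for two-muscle transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference for two-muscle transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and scientific setting

`cernaforge` implements the downstream regulatory analysis used in
comparative studies of oxidative (slow, red; e.g. chicken sartorius,
"SART") versus glycolytic (fast, white; e.g. pectoralis major, "PMM")
skeletal muscle: starting from per-class read-count matrices
(mRNA, lncRNA, circRNA, miRNA) for a small two-group design (four
biological replicates per muscle by default), it normalizes expression,
calls differential expression, applies the structural filters that
define lncRNA and circRNA candidate sets, assigns candidate cis-target
genes by a 10 kb proximity window, performs hypergeometric
over-representation analysis, and infers competing-endogenous-RNA
(ceRNA) triads — lncRNA–miRNA–mRNA triples in which a lncRNA and an
mRNA appear to titrate a shared miRNA.

Upstream steps — read alignment, transcript assembly, quantification,
coding-potential scoring, back-splice detection — are out of scope;
their outputs (counts, GTF, coding labels, back-splice tables) are the
pipeline's inputs. Because real inputs of this kind require large
sequencing archives, the package ships a seeded synthetic-data
generator whose outputs have the statistical structure the analysis
assumes, with a machine-readable truth ledger; every stage is tested
against that truth.

## Normalization and replicate consistency

mRNA and lncRNA counts are converted to FPKM,
$\mathrm{FPKM}_{fs} = 10^9 c_{fs} / (L_f T_s)$, with $L_f$ the summed
exon length and $T_s$ the sample's total assigned counts. The exact
conservation identity $\sum_f \mathrm{FPKM}_{fs} L_f T_s / 10^9 = T_s$
is asserted in the tests. circRNA back-splice junction counts and
mature miRNA counts are not length-proportional, so those classes use
CPM instead; every correlation downstream is computed per feature
across samples on $\log_2(x + 1)$, where a per-feature scale factor
cannot change the result, so the choice between FPKM and CPM does not
affect the network stage. Replicate consistency is summarized by the
Pearson correlation of $\log_2(\mathrm{FPKM}+1)$ between samples; on
the default synthetic fixture the mean off-diagonal correlation is
about 0.90, matching the well-replicated designs this analysis expects.

## Differential expression

The two-group test is a conditional negative-binomial exact test.
Counts are scaled to a common effective library size (geometric mean of
totals) and rounded. Writing $A$ and $B$ for the two group sums and
$\phi$ for a common dispersion, the conditional law of $A$ given
$A + B = s$ under the null is negative hypergeometric with weights
$\binom{a + n_1/\phi - 1}{a}\binom{s - a + n_2/\phi - 1}{s-a}$ — free
of the unknown mean — and the two-sided p-value sums all splits no more
likely than the observed one. At $\phi = 0$ this is the binomial
$\mathrm{Bin}(s, n_1/(n_1+n_2))$ split, which the tests exploit as an
independent oracle. The common dispersion is estimated by pooled
method of moments, $\hat\phi = \max\!\big(0, \sum (v - m) / \sum m^2\big)$
over features and groups. The fold change is
$\log_2((\bar{x}_2 + 0.5)/(\bar{x}_1 + 0.5))$ on scaled counts; the 0.5
pseudocount keeps all-zero groups finite. Significance uses the raw
p-value, strictly below 0.05, together with $|\log_2 FC| \ge 1$
(inclusive); a Benjamini–Hochberg option exists but is off by default
because the filter this pipeline reproduces is a raw-p rule. On 2 000
simulated null NB features (dispersion 0.1, 4 vs 4) the empirical
$p < 0.05$ rate is 0.047.

Group 2 (the oxidative muscle analogue, "SART") is always the fold-change
numerator, so "up" means higher in oxidative muscle.

## Candidate filters and the presence partition

lncRNA candidates are accepted when transcript length is at least
200 bp, the exon count is at least 2, and *both* coding-potential
predictors label the transcript noncoding; rejections are attributed to
the first failing rule in the fixed order length → exons → coding so
tallies are deterministic. circRNAs are retained when expressed (count
≥ 1) in at least two distinct samples, regardless of group. The Venn
("presence") partition counts a feature as expressed in a group when it
has a count of at least one in at least one sample of that group; this
definition is a package choice, as presence is rarely defined
explicitly in publications.

## cis-target assignment

A lncRNA is paired with every gene on the same chromosome whose gap is
at most the window (default 10 000 bp). The gap between 1-based
inclusive intervals is $\max(0, \max(s_A,s_B) - \min(e_A,e_B) - 1)$;
overlap counts as distance zero, and strand affects only the annotated
relative position (upstream/downstream on the gene's strand), not
eligibility. Published descriptions of the 10 kb rule are ambiguous
about inclusivity at exactly 10 kb; this implementation is inclusive
(`gap <= window`), the window is a flag, and the synthetic generator
never places a lncRNA in the [9.5 kb, 20 kb] band, so planted labels
cannot flip under either convention. The implementation is plain
interval arithmetic and is checked against a `GenomicRanges`-based
brute-force oracle on random annotations.

## Enrichment and the sponge test

Both enrichment and the sponge test are upper-tail hypergeometric
probabilities, $P(X \ge k)$, accumulated in log space. For term
enrichment the background defaults to all expressed genes, genes
without annotations stay in the background count, and a term is
significant at raw $p < 0.05$. For the sponge test on a (regulator,
mRNA) pair the population is the supplied miRNA universe (by default
the differentially expressed miRNA list), $K$ and $n$ are the miRNA
sets targeting each partner, and $k$ their overlap. The tail is exact
to double precision; tests compare it to exhaustive subset enumeration
for all populations up to 12 and to one-sided Fisher's exact tests at
$10^{-10}$ tolerance.

## ceRNA triads

A triad (lncRNA $L$, miRNA $m$, mRNA $G$) is emitted when all RNAs are
differentially expressed, $(m, L)$ and $(m, G)$ are miRNA–target edges
with Spearman correlation strictly below −0.7 (average ranks for
ties), $(L, G)$ has Pearson correlation strictly above 0.9, and the
sponge test for $(L, G)$ is significant strictly below 0.05. All three
thresholds are exposed as flags. Correlations are computed with the two
groups pooled (all eight samples): at $n = 4$ per group, within-group
correlation is essentially unmeasurable, and pooling is what makes
DE-coupled coexpression detectable. circRNA regulators pass through the
same gates when circRNA expression and target edges are provided. Each
triad additionally carries a descriptive `direction_consistent` flag
(regulator and mRNA moving together, miRNA opposite) — an annotation,
never a filter. miRNA–target edges come either from an imported table
or from canonical seed matching (default site type 7mer-m8, the exact
reverse complement of miRNA positions 2–8 in the target; 6mer, 7mer-A1
and 8mer available); there is no thermodynamic scoring.

## The synthetic-data generator

The generator emulates the eight-library two-muscle design: counts are
negative binomial with per-feature log-normal baseline means
(median 200 counts, log-sd 1.2), per-sample nominal library sizes drawn
from 0.8–1.2 million entering as relative depth factors, and dispersion
0.1 — typical of well-replicated bulk RNA-seq in livestock tissue
panels. A fraction `frac_de` of each class (default 10%) is planted as
differentially expressed with the group-2 mean multiplied by
$2^{\pm 2}$; planted ceRNA triad members are always differentially
expressed on top of that background, with the regulator and mRNA moving
together and the miRNA opposite.

Triad dependence uses a Gaussian copula rather than an additive latent
factor: each triad owns a per-sample standard-normal factor $z_s$, and
each member's NB quantile is drawn through
$x = \pm a z_s + \sqrt{1 - a^2}\,\varepsilon$ with loading
$a$ = `triad_corr_strength` (negative sign for the miRNA). This keeps
every marginal exactly $\mathrm{NB}(\mu, \phi)$ — an additive log-mean
factor strong enough to push sample Pearson correlations above 0.9 at
$n = 8$ inflates within-group variance so much that the members no
longer pass the differential-expression gate, making the two
requirements mutually exclusive — while giving the correlation gates
genuine planted positives. Triad-member baselines are floored at the
median expression level, reflecting that ceRNA crosstalk is a
phenomenon of reasonably expressed transcripts. Planted sponge overlap
is kept clean by drawing background miRNA–target edges only among
features outside the triads, so each planted pair shares exactly one
miRNA out of a DE-miRNA universe of ~45, giving sponge $p = 1/N < 0.05$.

Gene loci are laid out non-overlapping with fixed 60 kb spacing;
`cis_fraction` of lncRNAs sit beside a host gene with a gap uniform in
[0, 9 500] bp (at most one per flank, a capacity error otherwise), the
rest at least 20 kb from every gene. circRNAs are placed inside a host
gene; miRNA loci live on their own chromosome. Target sequences carry
at least one exact planted 7mer seed site per edge at a recorded
position, with chance background occurrences of planted seeds scrubbed
by a single-base change when they do not overlap another planted site.
One global seed drives fixed per-stage child seeds, and all emitted
files are byte-deterministic.

What the generator does *not* emulate: GC and length biases,
library-composition effects (hence no TMM-style normalization), isoform
complexity, read-level errors, and correlated gene programs beyond the
planted triads. Passing the planted-recovery tests therefore
demonstrates that the inference machinery is correct under its own
model assumptions, not that the thresholds are well-calibrated for any
particular real dataset.

## The permutation null

The negative control for triad inference shuffles the sample labels of
each RNA class *independently*, destroying the cross-class sample
alignment that Spearman/Pearson gates rely on; across ten shuffles of
the default fixture the pipeline emits zero triads. Permuting only the
group labels is not a valid null here: a 4-vs-4 relabelling that
overlaps the true grouping in three samples retains exactly half of a
planted $\log_2 FC$ of 2 — right at the inclusive DE boundary — while
pooled correlations do not depend on group labels at all, so planted
(true) signal would leak through any group-permutation control. The
ceRNA claim is about cross-RNA association; the misalignment null is
the null of that claim.

## Numerical and degenerate-input choices

Strict versus inclusive boundaries follow the printed rules exactly:
$p < 0.05$ strict, $|\log_2 FC| \ge 1$ inclusive, length ≥ 200 and
exons ≥ 2 inclusive, gap ≤ 10 kb inclusive, SCC < −0.7 and PCC > 0.9
strict, sponge and enrichment $p < 0.05$ strict. Constant expression
vectors make a correlation undefined: sample-correlation entries become
`NA` with a warning and candidate pairs are skipped with a warning,
never a crash. Zero-total samples, missing lengths, missing predictor
labels, and study genes outside the background are hard errors naming
the offenders. Hypergeometric and NB-exact tails are computed in log
space with a log-sum-exp reduction; the minimum-likelihood two-sided
rule uses a $10^{-7}$ relative tolerance when grouping tied outcome
probabilities, as exact-test implementations conventionally do.

## Problem sizes used in the tests

The shipped test-suite and acceptance script run the generator at its
default scale — 2 000 mRNAs, 400 lncRNAs, 200 circRNAs, 150 miRNAs,
30 triads, 4 + 4 samples — which the package treats as its reference
desk-scale study; unit fixtures use a 200-gene miniature. Typical
results at seed 1: DE sensitivity 0.996 with empirical FDR 0.077 on
the mRNA class, all 100 planted cis pairs recovered with no extras,
the planted term ranked first, 28/30 triads recovered, and zero triads
across ten permutation shuffles.

## Known limitations

Raw-p filtering (no multiplicity control by default) reproduces the
analysis convention but inflates family-wise error on large feature
sets; the BH option is available. The exact test uses one common
dispersion — no tagwise shrinkage — and common-library scaling rather
than TMM, so strongly composition-biased libraries are better served by
a dedicated DE framework. Seed matching ignores binding energetics and
conservation. The sponge test conditions on the supplied miRNA
universe, whose choice (DE miRNAs versus all expressed miRNAs)
materially changes $p$; it is a flag, and the default mirrors the
restricted universes used in practice. Cis-target assignment uses
transcript spans, not promoters, and ignores strand for eligibility.
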