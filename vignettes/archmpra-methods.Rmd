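---
title: "Methods: MPRA analysis of archaic introgressed variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MPRA analysis of archaic introgressed variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archmpra)
```

This vignette records the models, conventions and design choices behind
`archmpra`, in the spirit of a statistical methods supplement. The README
shows the user-facing workflow; here we explain why each stage is built the
way it is.

## Library design

A single-variant oligo is a 170 bp window of reference sequence with the
variant base at 0-based offset 85 (85 bp of context to the left, 84 to the
right). "Centred" admits two placements for an even margin; we place the
variant one base right of centre so that the guaranteed flank on either side
is at least 75 bp, which is how the assay's design is usually described.
Neighbouring variant sites inside a single-variant window always carry the
reference (modern) allele — a property that matters when interpreting
haplotype results, because a single-variant oligo for one SNP of a cluster
silently fixes its neighbours to the modern state.

Clusters of 2–6 SNPs within 170 bp additionally receive one oligo per
allelic combination (`2^n` sequences) on a window centred on the midpoint of
the outermost sites, clamped so every site sits at least 2 bp inside the
window. A cluster spanning more than 166 bp cannot satisfy this and is a
hard error rather than a silent split. The anchor choice is ours: the
midpoint keeps the combinatorial set on one shared window, which the
per-locus ANOVA requires.

Both adapters and the core are screened for SfiI (`GGCCNNNNNGGCC`) and BsiWI
(`CGTACG`) recognition sites, whose presence would truncate an oligo during
cloning. The recognition sequences come from standard enzyme catalogues.
Both motifs are reverse-complement palindromic, so one strand suffices.
Dropped oligos are reported rather than resurrected; a SNP can therefore
lose one allele and become untestable, exactly as in a real library.

Scrambled negative controls are uniform-random 170-mers accepted only if
they contain no PWM match at p < 1e-4, share no exact 24-mer with the
reference on either strand, and pass the restriction screen. The 24-mer rule
replaces an alignment-based genome screen: at this length an exact-match
test is deterministic, dependency-free, and stricter than default
seed-and-extend sensitivity.

## The measurement model behind the synthetic generator

The generator exists so that every downstream stage can be tested against a
known truth. Its defaults describe the assay this package targets:

* five replicate libraries over three lymphoblastoid cell lines — two
  European replicates and three Papuan ones (a fourth Papuan replicate is
  deliberately absent, mirroring a failed cDNA library);
* 48 barcodes per oligo on average (SD 40, log-normal, floored at 10);
* ~15% of SNPs in multi-SNP regions, mostly pairs;
* introgressed allele frequencies from a decreasing distribution truncated
  to [0.15, 1].

Counts follow a hierarchical negative-binomial model. Each barcode has a
Gamma abundance weight `a_b` (shape 4, mean 1) shared between fractions and
replicates; pDNA counts are `NB(mean = 200·a_b, dispersion 0.05)` and cDNA
counts `NB(mean = 200·a_b·2^(β0 + β_o + ε_r), dispersion 0.15)`, with
`β_o` the planted log2 activity of the oligo and `ε_r ~ N(0, 0.05)` a small
replicate shift. The shared abundance weight is what produces the familiar
pattern of high cross-replicate pDNA correlation alongside moderate
cDNA–pDNA correlation; the dispersion values were chosen once to reproduce
that qualitative pattern and are config-exposed. Library sizes are the
column sums plus a 10% unassigned remainder, as in real count tables where
not every read is assigned.

What the generator does **not** emulate: PCR jackpotting, barcode-sharing
artefacts, cell-line-specific *trans* effects beyond the scalar replicate
shift, and read-level errors (the package consumes barcode counts, not
reads). Passing tests on synthetic data therefore demonstrate correctness of
the statistics under this model, not robustness to every artefact of a real
experiment.

Scenario truths: `null` plants nothing; `default` makes ~10% of SNPs and
regions active at β in [1.5, 2.5], with ~9% of active single SNPs carrying
an allelic |log2 FC| ≥ 1 (the differential-activity rate the assay regime
suggests); `motif` plants differential activity by writing a PWM consensus
into the reference so one allele completes the site and the other breaks it;
`additive` draws per-site allele contributions and sets each haplotype's
activity to the exact sum of its constituents; `interaction` additionally
zeroes the constituent contributions of some regions while activating their
haplotypes, creating pure interactions. One global seed fans out to
deterministic per-stage child seeds.

## Normalisation, filtering, activity

Normalisation is `log2((count + pseudocount)·1e6 / library_size)` with a
default pseudocount of 1 on barcode-level counts. The pDNA floor filter
(mean pDNA log2 CPM < −5 across replicates) is applied to pseudocount-free
log2 CPM so the published threshold keeps its meaning; both constants are
config-exposed because the original normalisation's pseudocount convention
is not documented anywhere we could verify. The barcode filter runs before
the oligo filter (< 10 surviving barcodes), and re-running the filters on
filtered output is a no-op.

Activity of a barcode is its cDNA minus pDNA log2 CPM. The per-replicate
activity test is a one-sample, one-sided (greater) *t* test of an oligo's
barcode activities against the replicate mean activity `μ_r`, treated as a
known constant — the alternative (a two-sample test against all other
barcodes) is also defensible, but the constant-μ reading matches the way the
test is described and makes `μ_r` a simple, reproducible quantity. `μ_r`
includes the tested oligo's own barcodes; at library scale the bias is
negligible and the contract simpler. Degenerate conventions: fewer than two
barcodes → untestable (NA, counted as not significant); zero variance → p =
0 / 0.5 / 1 as the mean is above / at / below `μ_r`.

BH correction is applied within each replicate (one family per replicate),
because the consensus rule — active when adjusted p < 0.05 in ≥ 2 of 5
replicates — is built from per-replicate decisions. Ancestry specificity
follows fixed patterns (significant in both European replicates and no
Papuan one, or in ≥ 2 of 3 Papuan replicates and no European one); patterns
matching neither rule are SHARED when active.

## The allelic model

Counts are summed across an oligo's barcodes per replicate (aggregation
stabilises the ratio and is the recommended input for precision-weighted
MPRA models), with a 0.5 aggregate pseudocount. For each SNP we model the
ten oligo-by-replicate log ratios with intercept, allelic state and genetic
background covariates. Precision weights come from a global lowess trend of
the square-root residual standard deviation (from an unweighted first pass)
on mean pDNA abundance: pDNA abundance measures element dosage, and dosage
drives the precision of a ratio, which is why the trend covariate is pDNA
rather than cDNA. Weights are the predicted standard deviation to the −4th
power, i.e. inverse predicted variance.

Residual variances are shrunk by moment matching on `log s²` (the standard
closed forms with digamma/trigamma; the trigamma inverse is solved by Newton
iteration). If matching fails (non-positive excess variance), the prior
degrees of freedom are infinite and a pooled variance is used. The moderated
*t* uses `d0 + df` degrees of freedom, two-sided p-values, and BH across all
tested SNPs. The log2 fold change is reported with the convention that
negative values mean the archaic allele is more active.

Only single-variant SNPs with at least one active allele enter differential
testing in the pipeline, matching how such assays restrict the allelic
question to sequences that show any activity at all; the function accepts an
explicit SNP list so calibration studies can test every SNP.

Haplotype loci get a per-replicate one-way fixed-effects ANOVA across their
allelic combinations on barcode-level activities (at least two groups with
at least two barcodes), BH within replicate across loci, and the same
two-replicate consensus rule. Degenerate conventions: zero within-group
variance yields p = 0 when means differ and p = 1 when they do not.

## Motif scanning and exact p-values

Sequences are trimmed to their central 40 bp (for even remainders the
window starts at `floor((L−40)/2)`) because a variant sits at the window
centre and binding-site disruption is a local question. Scanning is
log2-odds against the motif background at every offset on both strands; the
per-motif, per-allele score is the maximum.

P-values are exact: per-column scores are discretised at 0.01 bits and the
null score distribution under the background model is built by convolution
across columns. The p-value error is bounded by the probability mass within
`L × granularity` of the threshold. Zero-probability motif entries score
−Inf; sequences hitting them are excluded from every finite tail, so below
the smallest finite score the tail equals the total finite mass (1 for
full-support motifs). A differential binding record is kept when one allele
matches at p < 1e-4 and the other at p < 1e-3, and the motif with the
largest absolute score difference is reported. The background defaults to
uniform and is taken from the MEME file when present.

## Downstream statistics

Frequency deciles are assigned within each stratum (source × allelic state)
by stable rank, decile 1 holding the highest frequencies; each decile's
active percentage is compared to the stratum rate with an exact two-sided
binomial test (small per-decile counts make the normal approximation
unreliable), and an F-test of per-decile percentages on decile number
screens for an overall trend. Fewer than ten sequences or ten distinct
frequencies collapse the binning with a warning.

Depletion at IAF thresholds uses Fisher's exact test; both the
conditional-MLE odds ratio and a 0.5-corrected sample odds ratio are
reported because zero cells leave the former without a finite CI.

TSS distances are signed and strand-aware (downstream of the gene positive),
measured from the SNP position; equidistant ties resolve to the upstream TSS
and are flagged. Chi-square tests (no continuity correction, so statistics
match the textbook formula) compare activity within vs beyond 1 kb, and a
logistic regression of activity on allelic state is run within 1 kb.

Haplotype concordance is restricted to 2-SNP regions with all four
single-variant oligos measured; archaic–archaic combinations are excluded
from the single-vs-haplotype comparison because no single-variant
counterpart exists (singles are built on a modern background). The pairing
convention — each haplotype sequence paired with each constituent single
carrying the same allele — is ours; the quantity of interest (concordance
percentage per allelic class and its homogeneity) does not depend on the
direction of the pairing. Additivity compares each haplotype's
median-over-replicates activity with the sum of its allele-matched singles'
per-replicate median activities (median over replicates of the per-replicate
sum); haplotypes called active while every matched constituent is inactive
are flagged as interaction candidates. Constant per-replicate offsets cancel
from neither axis, but they are common to all regions and therefore affect
the intercept, not the slope.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the full pipeline on panels of
~850 SNPs (~2,000 oligos, ~90,000 barcodes, 5 replicates), which we chose as
the smallest scale at which decile profiles, haplotype statistics and
empirical-Bayes hyperparameter estimation are all well-conditioned; unit
tests use panels of 25–150 SNPs. Calibration and recovery checks aggregate
over three seeds. All coordinates are 0-based half-open internally. The
lowess trend uses a span of 0.5 and is floored at 1e-4 before inversion to
weights. BH adjustment, t tests, ANOVA, Fisher, binomial, Wilcoxon,
chi-square and logistic fits are delegated to R's stats package; the
moderation, trend weighting, PWM dynamic programming and design
combinatorics are implemented here and verified in the test suite against
brute-force oracles (step-up BH, closed-form normal equations, full `4^L`
enumeration, hypergeometric sums).

## Known limitations

* The allelic model ignores replicate random effects beyond the fixed
  background term; a large replicate shift inflates residual variance and
  makes the moderated test conservative. The generator's replicate SD (0.05
  log2 units) reflects a well-behaved experiment.
* The activity test treats `μ_r` as a constant; with few retained barcodes
  per replicate the neglected uncertainty in `μ_r` is not negligible.
* Scrambled-control generation is rejection sampling; extremely dense motif
  collections can make the acceptance region small (the error after 1,000
  rejections suggests loosening the motif set).
* The synthetic TSS annotation places one TSS per SNP unit, so TSS-distance
  statistics are exercised but gene-density effects are not modelled.
* Multi-window SNPs: when a SNP belongs to one haplotype region and its own
  single-variant pair, differential summaries treat the single-variant pair
  as authoritative; haplotype evidence appears only through the per-locus
  ANOVA.
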