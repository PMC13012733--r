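# archmpra

Analysis of massively parallel reporter assays (MPRAs) that test the
regulatory activity of archaic introgressed variants.

## The problem

Modern human genomes carry sequence inherited from Neanderthals and
Denisovans. Whether an introgressed variant changes gene regulation can be
tested experimentally with an MPRA: thousands of 170 bp candidate sequences
are synthesised, tagged with random 15 bp barcodes, cloned upstream of a
reporter, and transfected into cell lines. For every barcode, the ratio of
its abundance in the reporter cDNA to its abundance in the plasmid DNA
(pDNA) input measures the regulatory activity of the attached sequence.

`archmpra` implements the complete analysis for libraries that pair each
introgressed (archaic) allele with its modern human counterpart:

* **Library design** — single-variant oligos centred on each SNP (variant at
  core offset 85, reference sequence elsewhere), all `2^n` allelic
  combinations for clusters of up to six SNPs within 170 bp, adapter
  attachment (`5'-ACTGGCCGCTTGACG … CACTGCGGCTCCTGC-3'`, 200 bp total),
  SfiI/BsiWI restriction-site screening, and motif- and genome-free scrambled
  negative controls.
* **Count processing** — log2 CPM normalisation, removal of barcodes with
  mean pDNA log2 CPM < −5 across replicates, removal of oligos left with
  fewer than 10 barcodes, and barcode-level activity
  `log2 CPM(cDNA) − log2 CPM(pDNA)`.
* **Activity calling** — per replicate, a one-sided one-sample *t* test of an
  oligo's barcode activities against the replicate mean; Benjamini–Hochberg
  correction within replicate; a sequence is active when adjusted p < 0.05 in
  at least two of the five replicates, with European/Papuan-specific classes
  derived from the per-replicate pattern.
* **Allelic differential activity** — for each SNP, cDNA and pDNA counts are
  summed across barcodes per oligo and replicate, and the log ratio
  `y = log2 CPM(Σ cDNA) − log2 CPM(Σ pDNA)` is modelled as

  `y = β0 + β_allele·allele + β_bg·background + ε`,

  by weighted least squares, with precision weights from a global
  mean–variance trend in pDNA abundance (the voom idea) and residual
  variances shrunk by empirical-Bayes moment matching (moderated *t*,
  `s̃² = (d0·s0² + df·s²)/(d0 + df)`). The reported log2 fold change is
  negative when the archaic allele is the more active one. Haplotype-like
  sequences are tested per locus with a one-way ANOVA across allelic
  combinations, again with the two-replicate consensus rule.
* **Motif analysis** — MEME-format PWMs, log2-odds scanning of the central
  40 bp of each allele on both strands, exact score p-values by dynamic
  programming over the discretised null score distribution, and a
  differential binding score (archaic − modern best score) for SNPs where one
  allele matches at p < 1e-4 and the other at p < 1e-3.
* **Annotation statistics** — introgressed-allele-frequency decile activity
  profiles with exact binomial tests, Fisher depletion tests at IAF
  thresholds, strand-aware TSS-distance profiles, GC association,
  single-vs-haplotype concordance with chi-square homogeneity tests, and
  haplotype additivity against summed single-variant activities.
* **Synthetic data** — a generator that emulates the assay (5 replicates
  across 3 cell lines, 48 ± 40 barcodes per oligo with a floor of 10, ~15% of
  SNPs in multi-SNP regions, IAF ≥ 0.15, negative-binomial counts with
  Gamma barcode abundances) with planted ground truth, so every stage is
  testable without any sequencing data.

## Worked example

```r
library(archmpra)

bundle <- make_fixtures("default", seed = 42)   # synthetic assay with truth
res <- run_pipeline(bundle, outdir = "results/default_run")
#> filter: 0 barcodes and 0 oligos removed; 90609 barcode rows retained
#> activity: 185 of 1907 oligos called active
#> differential: 8 of 82 SNPs differentially active
#> haplotype: 0 of 61 regions differentially active
#> recovery: activity_sensitivity=0.974 activity_fdp=0.000
#>           differential_power=1.000 differential_fdp=0.000
#>           logfc_slope=1.007 logfc_r=0.984

print(res$diff)
#> Moderated allelic differential-activity fit
#>   SNPs tested: 82  untestable: 0
#>   prior df d0 = 51.48, prior variance s0^2 = 1.04
#>   differentially active (q < 0.05 ): 8

head(res$diff$table[order(res$diff$table$p), c("snp_id", "logfc", "t", "q")], 3)
#>      snp_id     logfc         t            q
#> 1  snp00008 -1.964175 -26.02262 6.212972e-32
#> 27 snp00213  1.812056  23.26734 1.224786e-29
#> 40 snp00364  2.008287  21.10761 1.339436e-27
```

About 10% of planted sequences are active; 82 SNPs have at least one active
allele and enter allelic testing; 8 show differential activity. The top SNP's
`logfc = −1.96` means its archaic allele drives roughly four-fold higher
reporter activity than the modern allele (negative = archaic more active).
The recovery report compares every call against the planted truth. The
weights normalise residuals, so a prior variance near 1 indicates a
well-behaved mean–variance trend.

Each stage writes a TSV into `outdir` (`activity_calls.tsv`,
`differential_activity.tsv`, `haplotype_anova.tsv`, IAF/TSS/GC/concordance
tables) together with a `run.log` of counts in and out.

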