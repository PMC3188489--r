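---
title: "Repeat-aware bacterial transcriptomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat-aware bacterial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frankiatx)
```

This vignette is the package's account of the science behind each stage of
the pipeline: the models and their assumptions, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the design
choices made where the design was genuinely open.

## The setting

The pipeline targets single-end RNA-seq of a bacterial genome dense in
insertion-sequence (IS) transposase paralogs, patterned on the
actinobacterium *Frankia* sp. CcI3: a ~5.4 Mb genome with over 200
transposase genes, several paralog families above 98–99 % nucleotide
identity (one IS4 family with 14 nearly identical copies), heavy residual
rRNA/tRNA after depletion, libraries without technical or biological
replicates, and per-sample read lengths that differ between sequencing runs
(~76 nt for the three-day cultures, ~34–36 nt for the five-day culture; the
generator takes read length per condition as a parameter rather than fixing
one of the printed values).

## The synthetic-data generator

`simulation_config()` / `generate_genome()` / `ground_truth()` /
`simulate_reads()` emulate, at desk scale, the features of that setting
that stress the analysis:

* **Conditions.** Three culture conditions, `3dNH4`, `3dN2`, `5dNH4`, with
  per-condition read lengths (76/76/35 nt), read counts and rRNA/tRNA
  carry-over fractions (0.80/0.80/0.51 of reads — the three-day libraries
  carried ~80 % non-coding reads, the five-day one ~51 %).
* **Scale.** The default genome is 200 kb with ~140 features rather than
  5.4 Mb with 4,499 CDS. All statistics the pipeline computes (shares,
  RPKM, proportions) are scale-free; the tests and the acceptance script
  state the problem sizes they use (up to 400 kb and 10⁶ reads for the
  expression-recovery check), chosen so the whole suite runs in minutes.
* **Paralog families.** A family is `size` copies of one template. With
  `identity < 1` each copy is mutated at rate `(1 - identity)/2`, giving
  the requested expected pairwise identity. With `identity = 1` and
  engineered *diagnostic columns*, a subset of copies (`n_carriers`,
  default 6 of 14) shares an alternative base at those columns — the
  sequence structure that lets a mapper distinguish a sub-family only
  where a discriminating nucleotide falls inside the read.
* **Expression.** Per-feature weights are log-normal (meanlog 0, sdlog 1),
  a conventional model for the wide dynamic range of bacterial transcript
  abundance. Condition multipliers apply per functional class; defaults
  plant the study's qualitative pattern (transposases ×1.35 in `3dN2` and
  ×1.30 in `5dNH4`, mirroring the ~30 % higher summed transposase RPKM in
  the older and N₂-fixing cultures; nif genes ×2.5 in `3dN2`). Expected
  read shares are proportional to weight × length, as in a fragmenting
  library where molar abundance times transcript length sets read yield —
  so the per-gene weight is exactly what RPKM estimates.
* **Reads.** Multinomial feature counts, uniform starts within the
  feature, random strand (the library is unstranded), constant Q30
  qualities by default. Reads are error-free by default: the optional
  `error_rate` knob represents the reverse-transcription error (~3×10⁻⁵
  per base in the original chemistry) when needed; keeping it at 0
  isolates mapper and filter logic in tests. A configurable fraction of
  deliberately low-quality reads exercises the SNP read-quality criterion.
* **Variants.** Spikes are specified per locus on the coding strand and
  emitted with probability equal to the allele fraction in every
  overlapping read.

What the generator does **not** emulate: sequencing error profiles and
quality decay along reads, GC or positional coverage bias, operon
structure and intergenic (antisense/sRNA) transcription (an intergenic
read fraction is deliberately absent by default), rRNA-depletion
chemistry, paired-end reads, and cell-to-cell heterogeneity of the hyphal
growth habit. Passing tests therefore demonstrate correctness of the
*analysis logic* under a clean generative model, not robustness to every
artefact of real libraries.

## Read mapping

The mapper enumerates **all** candidate sites of a read at the best
(minimal) Hamming mismatch tier, on both strands, using a hashed k-mer
index and pigeonhole seeding: with `max_mismatches = m`, the read is probed
with `m + 1` non-overlapping chunks of the index k-mer length, so every
site with at most `m` mismatches is guaranteed to be found when
`(m + 1) · k ≤` read length. Defaults are `k = 11` and `m = 2`, chosen so
the guarantee holds even for the 34–36 nt short-read condition.
Indel-free alignment is sufficient for the generator's reads and keeps the
brute-force scan oracle exact; the tests compare candidate enumeration
against that oracle on small genomes.

The ambiguity policy mirrors the original mapping conditions: one
candidate is `unique`; 2 to `ambiguity_cap` (default 10) tied candidates
are placed uniformly at random; beyond the cap the read is discarded as
too ambiguous. Three open points were settled here as follows:

* "best-hit tie" is read as *ties at the minimal mismatch count*, the
  standard best-tier semantics;
* the cap applies to the total candidate count across both strands;
* a read overlapping two features is counted for the feature containing
  its 5′ start — an unambiguous single-count rule.

A 14-copy identical family under this policy is invisible except within a
read length of its diagnostic columns: interior reads tie at 14 > 10 sites
and are discarded, reads spanning a diagnostic column tie at 6 (carriers)
or 8 (non-carriers) sites and are assigned. This reproduces the
observation that two-thirds of such a family shows no reads at all while
coverage concentrates around the discriminating nucleotides.

## Quantification

RPKM_g = C_g / ((L_g/1000) · (N/10⁶)) with L the annotated ORF length.
With `exclude_ncrna = TRUE` (default) the denominator N counts only reads
assigned to non-rRNA/tRNA features, so libraries with 50 % versus 80 %
ribosomal carry-over remain comparable; the exclusion rescales every
coding RPKM by the same factor and is therefore order-preserving.
Discarded-too-ambiguous reads were never assigned and appear in no
numerator or denominator. ncRNA features still receive an RPKM value
(against the coding denominator) so tRNAs can be ranked in top-N tables —
ribosomal RNAs are omitted from those tables by default, tRNAs are not.
Read-level ncRNA removal and denominator-level removal are treated as
identical here; they differ only if a read maps partially into an ncRNA
feature, which the 5′-start counting rule excludes by construction.

## Differential expression

Without replicates, between-library comparison falls back on the
two-proportion z-test on pooled counts (Kal's test): genes are compared as
proportions of their library's coding reads, the same denominator used for
RPKM. The implementation is checked against an independently coded 2×2
Pearson chi-square through the identity z² = X², and calibrated under a
Poisson null (rejection rate 0.05 ± 0.01 at α = 0.05 across 10⁴ genes).
Raw p-values are reported by default because the original analysis flags
raw p > 0.05 with an asterisk; Benjamini–Hochberg adjustment is available
via the `adjust` argument. Both fold renderings are supported: raw ratios
(0.54-style) and signed folds (−1.02-style, magnitude always ≥ 1). Genes
with a zero count in exactly one library have an infinite ratio and are
excluded from up/down summaries rather than distorted by a pseudocount
(a pseudocount remains available). rRNA/tRNA rows are excluded from
comparisons: they are not part of the coding denominator.

## Heat-map clustering

Expression is log₂(RPKM + 1); the pseudocount of 1 handles RPKM 0 and was
chosen because the log base and offset were not specified in the original
pipeline. Rows are centred on their median, so the rendered map is black
at a gene's median expression, red above, green below. Both axes are
clustered hierarchically with 1 − Pearson correlation distance and average
linkage — the defaults of the clustering-program family the original
analysis used — and the gene tree is cut at the smallest height yielding
five groups (`cutree(k = 5)`), the number of visually delineated groups in
the original map. "Normalisation" beyond median subtraction is
interpretable as per-gene variance scaling; it is implemented
(`scale_rows`) but off by default. Rows that are constant after centring
carry no shape information; their correlation to varying rows is treated
as 0 (distance 1) and to each other as 1 (distance 0).

## Variant calling

The pileup expresses every observation on the forward reference strand
(reverse-strand alignments contribute complemented bases). The filter
cascade applies, in order: reads with mean quality below 15 are dropped
(strict `< 15`, a literal reading); variant-base observations must exceed
quality 20 strictly; at least 10 observations must remain; and the variant
must reach 25 % of them. Coverage and fraction are evaluated **after** the
quality filters — the criteria are listed as a cascade, and the 25 %
denominator is post-filter coverage. The most frequent non-reference base
is the variant; further alternatives enter the variant set only if they
pass independently, matching the biallelic variant pairs of the reported
tables. Codon effects are annotated strand-aware from the annotated
translational start; the three-letter amino-acid rendering
(`Arg -> Gln`) matches the reported format, with `-` for synonymous
changes. Intersection across samples is keyed by genome position with
variant sets unioned; it is order-independent and associative.

## Genome context

Transposase density uses ORF midpoints in a 250 kb moving window.
Deletion windows are *inputs* (previously defined regions of active
deletion), never inferred. Enrichment classifies each transposase ORF by
RPKM strictly above the sample median (the dashed-line threshold of the
genome-wide plot) × midpoint inside any window, and applies a 2×2 Pearson
chi-square without continuity correction (df = 1), the construction
consistent with the z² identity. Because the original chi-square
construction is not fully specified, a goodness-of-fit variant against the
windows' genome fraction and a permutation p-value are also provided; the
2×2 test is the default, and the originally printed p-value is not used as
a reference quantity for this reason. Midpoint containment decides window
membership for ORFs straddling a boundary.

## RT-qPCR quantification

Primer efficiency is the fold amplification per cycle, E = 10^(−1/slope)
of the Ct versus log₁₀(template) standard curve (E = 2 for perfect
doubling; assays outside (1, 2.2] are rejected). Relative expression uses
the Pfaffl standardisation against the reference gene (glnA):
R = E_t^(ΔCt,t) / E_ref^(ΔCt,ref), with ΔCt = Ct(calibrator) − Ct(sample)
so that higher expression in the sample yields R > 1, matching the
"fold increase" orientation of the reported figures. With E = 2
throughout, R reduces to 2^−ΔΔCt exactly. Standard errors are propagated
from triplicate Ct variances by the delta method on log R; reference-gene
variance is included by default and can be excluded, since the original
error bars do not state whether they propagate it.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive throughout (GenBank convention),
  converted only at the FASTQ/SAM/VCF boundaries as those formats require.
* Determinism: every generator and the tie-placement RNG are seeded;
  candidate lists are sorted (position, strand) before the uniform draw so
  the chosen site is platform-independent.
* Degenerate z-test columns (both counts zero, or pooled proportion 1)
  report z = 0, p = 1 with a flag rather than NaN.
* Degenerate enrichment margins report p = 1 with a warning.
* All-zero gene rows are dropped before clustering with a message.
* Zero requested reads yields an empty FASTQ with a warning.
* Ranking ties in top-N tables break by locus tag for reproducibility.

## Known limitations

* The mapper is Hamming-only (no indels, no quality-aware scoring) and is
  not intended to reproduce any commercial aligner bit-for-bit — only the
  stated ambiguity policy.
* The clustering reproduces the *procedure*, not the original gene-to-group
  assignments of the real data, which depend on the unreleased raw reads.
* SNP calling has no genotype likelihoods, indels or strand-bias test; it
  is the stated filter cascade and nothing more.
* The packaged worked-example tables are the published summary tables; the
  raw sequencing data they derive from are not redistributed here, so
  dataset-scale numbers (total read counts, per-sample SNP totals) are
  exercised on synthetic constructions instead.
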