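---
title: "Linking chromatin accessibility, TF motifs, and expression with chromlink"
author: "chromlink authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking chromatin accessibility, TF motifs, and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromlink)
```

# Scope and model

`chromlink` integrates three layers of regulatory genomics data at desk
scale: chromatin accessibility peaks (ATAC-seq), transcription-factor
binding peaks (ChIP-seq), and gene-level expression. The package starts
from *called peaks* and *count/abundance matrices*; read alignment, peak
calling, and differential-expression testing are upstream tools' jobs and
are deliberately out of scope. Every coordinate is handled 0-based
half-open internally, the BED convention, with the GTF reader converting
from 1-based inclusive.

## The fractional-overlap rule and peak-set partitions

Two peaks $a$ and $b$ on the same chromosome overlap by
$\omega = \max(0, \min(a_e, b_e) - \max(a_s, b_s))$ bp. They are declared
*overlapping* when

$$\omega > f \cdot |a| \quad \text{or} \quad \omega > f \cdot |b|,$$

with $f = 0.5$ by default and a strict inequality. The disjunctive
("either peak") reading was a genuine design choice: the phrase "greater
than 50% of the length of either peak" admits a conjunctive reading too.
We implement the inclusive one — it matches the common
reciprocal-fraction-with-either semantics of interval tools, and it is the
more permissive rule, so shared regions are never under-counted — and
expose `mode = "both"` for the conjunctive alternative. `partition_peaks()`
classifies every peak of set A as shared (≥ 1 qualifying overlap in B) or
unique, and symmetrically for B; outputs are sorted (chromosome, start,
end) so runs are reproducible. Candidate pairs come from an interval index
(`IRanges::findOverlaps`), with the fractional rule applied to each pair;
the test suite and acceptance script check the result against an all-pairs
brute-force oracle on hundreds of random instances.

## Peak annotation

Peaks are classified by their *center* — the narrowPeak summit when
present, otherwise the floor midpoint — with priority
promoter > TTS > exon > intron > intergenic. Center-based classification
makes the five categories a partition of any peak set, which whole-interval
overlap would not. The promoter window is strand-aware,
$[\mathrm{TSS} - 1000, \mathrm{TSS} + 100]$ bp by default, and the TTS
window is ±100 bp; these are HOMER-like defaults, configurable via
`annotation_config()`, since annotation-window sizes are rarely printed in
publications. UTRs are not distinguished from exons. "Enhancer" means
exactly intronic or intergenic. Nearest-gene assignment minimises
|center − TSS| on the same chromosome, breaking ties toward the
lexicographically smallest gene id.

## Motif scanning and enrichment

Motifs are IUPAC consensus strings (exact ambiguity-code matching; an `N`
in the *sequence* matches only the consensus code `N`, so unsequenced bases
never create hits) or 4×width probability matrices scored as log2
likelihood ratio against a uniform 0.25 background, with a per-motif bit
threshold and 0.001 pseudocount. Both strands of the ±50 bp window around
each peak center are scanned; a peak is a *carrier* when its window holds
at least one hit (presence/absence — hit counts do not change enrichment).

Enrichment of a target set against an explicit background set pools both
into a population of $N$ peaks with $K$ carriers and computes the
cumulative hypergeometric upper tail $P(X \ge k)$ for the $k$ carriers
among $n$ target peaks, evaluated in log space (`stats::phyper`,
`log.p = TRUE`) for stability at extreme significance. The background is a
user-chosen peak set (the comparison condition), not GC-matched random
genomic draws — the method compares condition peak sets directly, and GC
matching is out of scope. Motifs are ranked by $\ln p$ (the base only
affects display, never ranks), ties broken by name so ranking is
order-independent, and `rank_differential()` reports
$\mathrm{shift} = \mathrm{rank}_A - \mathrm{rank}_B$ per motif, sorted
descending — the waterfall comparison.

## Peak-to-gene integration

`link_peaks_to_genes()` connects a peak to every gene whose TSS lies
within 50 kb (inclusive) of the peak center. Distance is measured to the
TSS rather than the gene body: the source rule states only a distance to
the peak center, and the TSS anchor is strand-aware and consistent with
the annotation module; `anchor = "body"` is available. A gene is
*activated* when it links at least one gained (newly accessible) peak and
its log2 fold change is strictly above +1; *repressed* with a lost peak
and log2FC strictly below −1. "Newly accessible" is defined
set-theoretically through the partition's unique regions, not by
differential signal testing. A gene qualifying for both classes (possible
only with unusual thresholds) is reported `unchanged` with a conflict
flag rather than silently resolved. No significance filter is applied on
top of the fold-change cutoffs, since none is specified with the rule.

## Normalization, z-scores, and signatures

Size factors are classical median-of-ratios: genes with any zero value are
excluded from the reference set; each remaining gene's reference is its
geometric mean across samples, and a sample's factor is the median ratio
to the reference. The per-gene z-transform uses the population (n
denominator) standard deviation — the transform feeds visualization and
scoring, not inference, and the choice is applied consistently; zero
variance genes become all-zero rows with a warning. Fold changes are
$\log_2((\bar x_B + 1)/(\bar x_A + 1))$; the pseudocount of 1 (used for
the log2 transform as well) is exposed everywhere.

Signature scores are *raw sums* — of per-gene z-scores, or of
$\log_2(\mathrm{FPKM}+1)$ — over the signature genes found in the matrix,
matching the published formulas; a per-gene-normalized mean is available
behind `normalize = TRUE` for cross-signature comparison. Missing genes
are skipped, never imputed, and the found-gene count is attached to every
result, because raw sums are only comparable at equal coverage.
`derive_signature()` intersects two or more cistrome-annotated gene sets
and keeps consensus genes with log2FC strictly above 2; "significantly
higher expression" is operationalised as that fold-change filter alone,
as no p-value criterion accompanies the printed rule. Over-representation
(`ora()`) shares the same hypergeometric kernel and adjusts across
pathways with Benjamini–Hochberg — a standard choice where the source
reports FDR panels without naming a procedure. The constituent gene lists
of published scores (AR, EZH2, ASCL1 signatures) are user inputs, not
shipped constants.

# The synthetic-data generator

`simulate_study()` emulates the shape of a two-condition study so that
every operation can be validated against planted truth without any
external data. Defaults, chosen once as the study conditions:

| knob | default | why |
|---|---|---|
| genome | 2 × 500 kb, uniform A/C/G/T | large enough for 200 genes plus 200 peak loci with 50 kb linking headroom |
| genes | 200, spans 1–3 kb, 2–4 exons, random strand | compact models exercising every annotation category |
| peaks | 100 shared + 50 unique per condition, widths 200–600 bp | typical ATAC peak widths; shared copies jittered < ¼ width so pairs pass the 50% rule |
| planted motif | E-box `CAGCTG` | the canonical basic helix-loop-helix binding site; palindromic, so both strands are exercised |
| carrier rates | 0.6 in condition-B-unique peaks, 0.05 elsewhere | strong but not saturated target enrichment over a realistic background rate |
| decoys | 14 degenerate consensuses, widths 6–8, 0–3 two-fold codes | a motif universe spanning a wide range of background frequencies, as in curated motif libraries |
| counts | NB, mean + α·mean², α = 0.05, means log-uniform 20–2000 | bulk RNA-seq-like dispersion and dynamic range |
| regulated genes | 10 activated + 10 repressed, planted log2FC ±2 | 10% DE, the regime where median-of-ratios stays unbiased |
| fold-change table | planted value + N(0, 0.25²) noise | the stated observation-noise condition; `planted` and `estimated` modes also available |
| signature | 50 genes, +1.5 cross-sample log2 sd in half the samples | the planted shift is expressed in units of each gene's NB-implied log2 sd, √(1/μ + α)/ln 2 |
| size factors | all 1 (study designs pass e.g. 0.5/1/2) | planted scale recovered by normalization |

Design decisions worth recording:

* **Motif planting writes the motif into the genome** inside carrier
  windows (for shared loci, inside the intersection of both conditions'
  windows), rather than rejection-sampling carrier windows. Truth is then
  finalised by *re-scanning* every window, so chance occurrences of the
  short motif are counted into the truth table and truth always matches
  the emitted FASTA.
* **Regulated genes are coupled to the peak design**: each activated gene
  receives a condition-B-unique peak centered within 50 kb of its TSS,
  each repressed gene a condition-A-unique peak, so the integration rule
  has an exact expected answer. All distinct peak loci are separated by
  more than a maximal peak width, making the partition truth exact by
  construction.
* **One named RNG stream per artifact kind** (genome, genes, classes,
  peaks, planting, decoys, expression, signature), all derived from the
  single master seed, so regenerating one artifact kind does not perturb
  the others and identical seeds give byte-identical text artifacts.
* Decoy motifs are rejected if IUPAC-compatible with the planted motif on
  either strand (in either containment direction); such decoys would
  inherit the planted enrichment and contaminate rank comparisons.

What the generator does *not* emulate — and what passing tests therefore
do not show: GC/dinucleotide sequence composition (real motif background
rates are composition-dependent), read-level noise and peak-calling
artifacts, overlapping genes and isoform structure, correlated
gene-gene expression, and batch effects. Recovery rates on this generator
are upper bounds on real-data behavior, not estimates of it.

# Numerical and validation choices

* Hypergeometric tails are computed in log space; the tests require
  agreement with full combinatorial enumeration to 1e-10 relative error
  for every configuration with N ≤ 30, and the two worked values
  13013/184756 and 499752/75287520 exactly.
* The problem sizes used by the validation suite and acceptance script —
  100 partition instances of 1,000 intervals per side, a 200-versus-2,000
  window motif experiment (500 per side for the two-condition rank
  differential, which needs larger targets for stable decoy ranks), 1,000
  genes with 50 + 50 planted regulated genes over ten seeds, 2,000-gene
  size-factor simulations over five seeds, and 1,000 randomized
  derivation instances — were chosen as the smallest designs at which the
  planted effects are unambiguous.
* Degenerate inputs fail loudly and early: empty target/background sets,
  matrices with no all-positive gene row, z-transforms of a single
  sample, signatures with no gene found, queries outside the ORA
  universe, infeasible genome packing.
* Ties are broken deterministically everywhere (motif name, gene id,
  coordinate order), and all writers emit canonical formatting so
  write-read-write cycles are byte-identical; same-seed pipeline runs are
  byte-identical end to end.

# Limitations

* The overlap predicate is pairwise presence/absence; fractional
  reciprocal *coverage* across multiple fragmented peaks is not
  accumulated.
* Gene models are gene-level only (the widest span per gene id); UTRs are
  folded into exons.
* Enrichment assumes target and background are disjoint peak collections;
  the functions do not deduplicate across the two sets.
* PWM scanning scores against a uniform background; composition-aware
  scoring and GC-matched backgrounds are out of scope.
* `ora()` is an over-representation test, not a rank-based enrichment
  (GSEA-style) statistic.
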