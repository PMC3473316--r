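---
title: "Pooled-sample SNV discovery: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-sample SNV discovery: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

poolsnv implements variant discovery from *pooled* transcriptome
resequencing: each sequencing library is made from mixed RNA of several
genotypes of one population group, so read counts at a site estimate
population allele frequencies rather than individual genotypes. The package
covers the full analysis path — read cleaning, pileup-based SNV calling,
gene-feature annotation, per-pool diversity statistics, cross-pool
comparisons and marker-panel selection — together with a synthetic-data
generator that produces pooled experiments with known truth, so every stage
is testable without external data.

## The calling model

Calling operates on per-pool pileup columns: for each reference position,
the read depth and summed Phred quality of every observed allele
(substitution bases, `+SEQ` insertions and `-L` deletions anchored at the
base preceding the event). Three thresholds define a call
(`call_params()`):

* **coverage floor** (`min_coverage`, default 6X): positions below it are
  not mined at all, and the number of positions at or above it is the
  covered length used as the denominator of SNPs/kb densities;
* **allele support** (`min_allele_reads`, default 3): an allele is
  *supported* only when at least three reads carry it, which suppresses
  sequencing-error singletons and doubletons;
* **call quality** (`min_quality`, default 70): with two or more supported
  alleles, the position is polymorphic only when every supported
  *non-majority* allele has a summed Phred quality of at least 70.

The quality is defined as the minimum summed base quality over supported
minority alleles. This is a deliberate realisation choice: the original
per-site quality of the upstream pipeline that inspired these thresholds is
not a documented quantity, so poolsnv uses only pileup-observable values
and exposes the threshold as a parameter. Three reads at Q30 clear the bar
(90 ≥ 70); three low-quality reads at Q20 do not (60 < 70) — exactly the
regime that separates genuine minority alleles from clustered low-quality
errors.

Positions with exactly one supported allele are retained as *monomorphic*
calls without the quality test. These never appear as variants on their
own, but they are what makes *fixed-difference* analysis possible: a site
fixed for different alleles in two pools is a between-pool variant even
though neither pool is polymorphic. Majority ties are broken
lexicographically, coordinates are 1-based inclusive everywhere, and `N`
or quality-0 bases are excluded from observations entirely (they do not
count toward depth).

Merging across pools (`merge_pool_calls()`) keeps one record per position
where at least two distinct alleles are supported across pools combined, or
where any pool is fixed for a non-reference allele. Each record carries
per-pool status (`polymorphic`, `fixed_ref`, `fixed_alt`, `no_call`,
`no_coverage`), per-pool depths and major-allele frequencies (MAF, in
[0.5, 1]; lower MAF means higher variability), and a global MAF computed
from supported-allele depths summed over covered pools.

## Read cleaning

`clean_fastq()` applies, in order: (1) discard reads with more than two
missing (`N`) calls or with mean quality below 15 over the first 10 bases;
(2) trim the 3' end; (3) discard reads shorter than 30 bases. The 3' rule
removes the last base while *any* trailing region of up to `tail_window`
(default 10) bases has a mean quality below 20, so no low-quality 3' region
up to the window length survives in the output. A plain trailing-window
test (stop as soon as the last-10 mean reaches 20) can retain several very
poor terminal bases behind a good buffer; the any-suffix form cannot, and
is idempotent: cleaning already-clean output changes nothing. The window
length is a free parameter — the rule the cleaning emulates is stated only
as "3' regions with mean quality lower than 20" — and is therefore
configurable. The attrition report accounts every input read to exactly one
fate (kept, missing-calls, head-quality, short).

## Diversity and pool-comparison statistics

Per pool, the summary table reports the ≥6X covered length, the polymorphic
SNP count, SNPs/kb (to one decimal) and the count and percentage of SNPs
with pool MAF below 0.7 — the conventional "highly variable" cut. MAF
histograms use right-closed bins of width 0.05 over [0.5, 1].

Two pools *share* a SNP when the position is polymorphic **within both**
(not merely detected in either); a position is *fixed-differential* when
each pool has exactly one supported allele and the two alleles differ.
Pools without coverage at a position are excluded from that position's
pairwise statistics rather than being treated as fixed-reference. The two
sets are disjoint per pair by construction. `shared_across_all()` reports
its count against both the SNP and the SNV denominator, since either total
may be quoted.

## Marker filters and panel selection

Markers destined for a genotyping assay pass a filter cascade:

* **VKS**: INDEL-kind variants are removed (INDELs dominate the error
  profile of short-read platforms);
* **intron distance (IS60)**: variants closer than 60 bp to an
  exon–intron junction of an overlapping gene are flagged. "Closer than"
  is read strictly: 59 bp flags, 60 bp passes. Variants in intron-free
  genes and intergenic variants are never flagged;
* **flanking polymorphism (CS60 / CS60_MAF(t))**: variants with another
  SNV within 60 bp are flagged, unless the neighbour's global MAF is at or
  above the threshold `t` — i.e. rare flanking variants can be tolerated
  near an assay primer. `t = 1` is the plain filter (every neighbour
  flags, including fixed-difference records whose global MAF is 1). All
  SNVs, including INDELs, act as flagging neighbours, since primer
  annealing is disturbed by any variant. The pass-set grows monotonically
  as `t` decreases.

Global (whole-collection) MAF is used for the neighbour test, matching the
single-MAF parameterisation of the filter-count tables; a per-pool variant
of the test can be built from the per-pool columns if needed.
`select_panel()` draws markers uniformly without replacement from the
candidates satisfying fixedness/differential criteria per pool, using an
explicit seed, because the selection step is otherwise irreproducible.
Marker informativeness uses the polymorphism information content
PIC = 1 − Σpᵢ² − Σ_{i<j} 2pᵢ²pⱼ², which never exceeds the expected
heterozygosity 1 − Σpᵢ².

The "variable in all groups" column of `filter_table()` counts markers
polymorphic in every pool; an alternative reading (pool MAF < 0.7 in all
pools) is computable from the same table but is not the default.

## The synthetic-data generator

`sim_config()` fixes the simulated study conditions. The defaults emulate a
pooled transcriptome experiment: 8 pools, 49-bp single-end reads, 30X mean
exonic coverage per pool, 1% mean substitution rate, 0.5% missing calls.
The toy genome (2 scaffolds × 32 kb, 16 three-exon genes per scaffold,
400-bp exons, 200-bp introns, 100-bp UTRs) is small enough that a full
8-pool run completes in well under a minute, yet large enough to plant
~230 variants at mutual distances over 60 bp.

Design features worth knowing:

* **Reads are exon-confined.** Reads are sampled uniformly within single
  exons and never span junctions, emulating unspliced cDNA-to-genome
  mapping — the regime in which no junction SNVs can be discovered. As a
  consequence coverage ramps linearly over the first and last 48 bp of
  each exon; truth variants are planted on the full-coverage plateau.
* **Quality-aware errors.** Base qualities follow a two-level model (~85%
  of body bases at Q30–40, ~15% at Q10–14, a decaying 3' tail floored at
  Q8). Substitution probability per base is proportional to `10^(-Q/10)`,
  rescaled so the mean equals `error_rate`; with `error_rate = 0` no
  substitutions occur. This Phred-faithful coupling is what makes the
  summed-quality threshold meaningful: clustered errors carry low summed
  quality and fail the Q70 bar, so the caller's precision comes from the
  thresholds, not from an unrealistically clean simulation.
* **Missing calls** are `N` with quality 0 — the base-space proxy for
  colorspace missing calls; colorspace chemistry itself is out of scope.
* **Low-coverage regions.** 8% of exons get a 0.1× depth multiplier — the
  same exons in every pool, emulating residual expression differences that
  survive cDNA normalisation (these are gene-driven, hence shared across
  pools). No truth is planted there, so the generator guarantees regions
  that fall below 6X and must yield no variants.
* **Variant classes** with pool-structured frequencies: `shared_all`
  (alternate frequency U(0.3, 0.7) in every pool), `pool_specific`
  (U(0.3, 0.7) in exactly one pool), `fixed_differential` (1.0/0.0 on a
  designated pool pair, 0 elsewhere), `background` (zero in each pool with
  probability 1/2, else U(0.2, 0.8)), `near_intron` (planted 48–59 bp from
  a junction, to exercise the intron-distance filter), `clustered` (pairs
  10–60 bp apart; the partner carries one uniform alternate frequency in
  U(0.05, 0.5) across pools so neighbour global MAFs spread over
  (0.5, 0.95) and the flanking filter's threshold has gradations to act
  on), and `indel` (1–2-bp insertions/deletions). All other placements are
  at least 61 bp from intron boundaries and from each other.

The per-pool frequency maps are exposed directly rather than derived from
a genotype-mixture model: with 5–15 genotypes per pool mixed at equal RNA
amounts the attainable frequencies form a lattice, but nothing downstream
depends on that granularity, so continuous frequencies give better test
coverage of the estimator.

What passing tests on this generator do **not** show: robustness to
mapping artefacts (alignment is out of scope; reads are emitted with known
true coordinates), to PCR duplicates, to strand biases, to colorspace
error structure, or to reference-genome incompleteness. The generator's
read attrition under cleaning (about 0.2% of reads discarded, mean clean
length ~46 bp in the default run) is far milder than what early
short-read chemistries produce under the same rules; the cleaning *rules*
are exercised fully, realistic *attrition* levels are not.

## Numerical choices and degenerate inputs

* Distance to an intron is the number of bases between the variant and the
  nearest intron base (0 inside an intron); intron-free genes give `NA`.
* `pool_maf()` on a two-allele tie returns 0.5; with more than two
  supported alleles the majority fraction can drop below 0.5.
* Zero-depth MAF, zero-length densities and frequency vectors not summing
  to 1 (tolerance 1e-6) are errors, not NaNs.
* Empty inputs (no reads, no variants, no genes) return empty, correctly
  typed results; a gene whose CDS lies outside its exons is rejected with
  a warning naming the gene.
* Variants overlapping several genes count once per gene in per-gene
  statistics and once in genome-wide totals.
* Feature-density denominators intersect the feature intervals with the
  ≥6X coverage mask, taken as positions covered in **at least one** pool —
  the space in which a variant could have been discovered at all.
* All randomness (genome, truth, reads, panel draws) derives from explicit
  seeds; per-pool read streams use a seed derived from `(seed, pool)`, so
  pools are independently reproducible and a fixed seed reproduces every
  output byte for byte.

## Problem sizes used in the test suite

The bundled tests run the full pipeline once under the default conditions
(8 pools × ~24,000 reads, ~230 planted variants) for the statistical
checks — recall and precision ≥ 0.95 for planted SNPs with pool frequency
in [0.2, 0.8], pool MAF within 3 binomial standard deviations of truth for
≥ 95% of sites, planted class counts recovered within ±10% — and once at
reduced size for byte-level determinism of all written outputs. Calling is
additionally verified against an independent brute-force implementation of
the rules on small random fixtures. These sizes keep the whole suite
around a minute on one CPU while leaving the binomial margins of the
statistical checks comfortable.

## Limitations

poolsnv estimates allele frequencies at the read level; it does not model
genotype likelihoods, linkage, or unequal RNA contributions of the pooled
genotypes (a genotype over-represented in the pool biases frequencies in
ways read counts cannot detect). Splice-aware pileups, realignment and
base-quality recalibration are out of scope, as are functional-effect
prediction and primer design itself.
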