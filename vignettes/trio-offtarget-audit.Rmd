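---
title: "Auditing Cas9 off-target effects by trio sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing Cas9 off-target effects by trio sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprtrio)
library(dplyr)
```

## The problem

When a zygote is edited with CRISPR-Cas9, two safety questions dominate:
did the nuclease cut anywhere it was not meant to (off-target mutations),
and did it leave complex damage at the intended site? Whole-genome
sequencing of the edited animal together with both parents (a trio) answers
the first question genome-wide: any well-supported variant in the offspring
that neither parent carries is a de novo mutation (DNM), and if Cas9 were
cutting promiscuously the DNM count would exceed the spontaneous
expectation, or DNMs would cluster near sequence-predicted guide-binding
sites.

The difficulty is that raw Mendelian-violation calls are dominated by
technical noise. In real trio data the large majority of raw candidates are
violations whose alleles are *present in the parents* — for example parents
genotyped AA and GG with the offspring called AA or GG instead of the
expected AG. These are genotyping errors, not mutations. `crisprtrio`
implements the full audit as a tested, reusable pipeline: consensus variant
filtering across callers, a DNM filtration cascade, guide off-target
enumeration with proximity annotation, structural-variant (SV) consensus
filtering, a binomial detection-power model, and a synthetic-trio simulator
with known ground truth to validate the whole chain end to end.

## Hard filters and caller consensus

Variant call sets from four callers are filtered independently and then
intersected:

* **Site filter (SF)** — quality-by-depth `QD > 2.0`, mapping quality
  `MQ > 30`, an allele-balance rule, and a strand-bias rule (Fisher's exact
  test on the ref/alt × forward/reverse table at p < 0.05; the test is a
  design choice, as hard-filter pipelines name no canonical test). All
  comparisons are strict: a value exactly at a threshold fails.
* **Genotype filter (GF)** — per-genotype depth `15 < DP < 100` and
  `GQ > 30`, again strict. A failing genotype in *any* trio member removes
  the site from that trio's analyzable set, because a DNM call needs all
  three genotypes. INDEL depth bounds default to the SNV bounds but are
  separate configuration keys.
* **Universal mask (UM)** — the union of mappability, low-complexity and
  repeat components; any record whose REF span intersects the merged mask is
  removed. Internally all intervals are 0-based half-open; VCF positions are
  converted at the boundary.
* **Consensus** — a variant is high-confidence iff a record with the same
  (chrom, pos, ref, alt) key survives in every caller's set, after indels
  are left-aligned and parsimony-trimmed so equivalent representations
  match. The key includes the alleles, not just the position, because an
  off-target audit is allele-specific.

Missing annotations are *unevaluable*, never failures: a record lacking QD
is flagged rather than silently discarded, so data problems surface instead
of vanishing.

### The allele-balance boundary

The allele-balance rule deserves its own paragraph because two conventions
collide at one point. The filter passes sites with `AB > 0.1` (allele
balance over the alt-carrying genotypes), backed by an exact binomial test
against 0.5; but the calling floor for mosaic variants is a minimum allele
frequency of exactly 10%, i.e. `ceiling(0.1 × DP)` mutant reads. At depth
40 the weakest callable mosaic has AB exactly 0.10: an inclusive boundary
(`AB ≤ 0.1` fails) would strike every variant sitting exactly at the calling
floor and make the filter cascade inconsistent with the binomial
detection-power model below. The default therefore fires the rule only when
AB is *strictly below* 0.1; `filter_thresholds(ab_inclusive = TRUE)`
restores the inclusive reading for users who want the harsher convention.
The rule also requires the binomial p-value to be significant, so genuinely
low-coverage sites are not struck on balance alone.

## The DNM filtration cascade

Candidates are detected per caller by a permissive genotype-configuration
rule: a site is a candidate iff the offspring genotype cannot be assembled
by drawing one allele from each parent. This detector deliberately replaces
a Bayesian trio-likelihood caller: the final call set is defined by the
downstream filters and the four-caller intersection, so the front end only
needs to be permissive and transparent, and a likelihood model would add an
opaque prior without changing the surviving set. The cascade then runs:

| stage | rule | removes |
|---|---|---|
| Raw | per-caller Mendelian violations | — |
| noStrict | intersection across callers | caller-specific false calls |
| AF | allele filtering: keep only candidates with an allele absent from both parents | the dominant noise class (parental-allele violations) |
| dbSNPF | absent from the known-variant database (allele-specific key by default) | known polymorphisms miscalled as de novo |
| CF | cross filtering: drop keys shared between siblings | systematic artifacts and miscalled inherited variants |

Each stage can only shrink the set, and each injected artifact class in the
simulator is removed by exactly one named stage, which is what the
class-labelled truth set tests.

## Off-target enumeration and proximity

The guide is a 20-nt protospacer; a candidate site is any 20-mer on either
strand whose 3'-adjacent 3-mer matches an allowed PAM (NGG, with NAG
tolerated) within a Hamming distance budget (5 for the primary screen, 7
for the extended screen; ungapped comparison only, since bulge models are
out of scope). Windows containing ambiguous bases are skipped. The scanner
is anchored in tests to a brute-force all-positions Hamming oracle on every
genome up to 50 kb and must recover 100% of simulator-planted sites at 0–7
mismatches.

Coordinates: `start` is the protospacer's 5' base on its own strand;
`fp_start`/`fp_end` give the 23-bp footprint as a genomic half-open
interval. The cut site is the blunt cut 3 bp 5' of the PAM (between
protospacer positions 17 and 18). A DNM is "near" a site when it falls
within 40 bp of the footprint — the window is measured from the footprint,
not the cut site or midpoint, a deliberate interpretation exposed as a
parameter. The read-level on-target (mosaicism) ratio is the fraction of
cut-site-overlapping reads carrying a deletion that intersects a ±5 bp
window around the cut; "near the PAM" is not a sharply defined distance, so
the window is configurable.

## Structural variants

Short-read SV calls pass when they are caller-PASS, breakpoint-precise,
supported by more than 10 reads and between 50 bp and 2 Mb (over-length
calls are auto-failed with a distinct review tag instead of a manual-
inspection step). Long-read calls require at least 10 supporting reads
*and* support exceeding 5% of the whole-region depth. Two callers are
intersected by reciprocal overlap: both overlap fractions must strictly
exceed 50%, with chained overlaps resolved greedily by best fraction.
Insertions have no interval extent, so they match by breakpoint distance
(≤ 100 bp) and length ratio — an extension beyond the interval logic,
config-gated. De novo SVs are what remains after removing anything
reciprocally overlapping a parental call, a known-database entry, or a
sibling call.

## Detection power for mosaic DNMs

A mutation arising before the first cleavage is expected in half the reads
(fraction 0.5); one arising in a single blastomere of the two-cell embryo
in a quarter (0.25). These fractions assume a heterozygous mutation and
unbiased read sampling. With depth $n$ and a minimum calling allele
frequency of 10%, a call needs $m = \lceil 0.1\,n \rceil$ mutant reads, and
the mutant read count is $X \sim \mathrm{Binomial}(n, p)$:

$$P(\text{miss}) = P(X \le m - 1) = \sum_{k=0}^{m-1} \binom{n}{k} p^k (1-p)^{n-k}.$$

```{r power}
power_model(depth = 40, stage = "two-cell")
```

At depth 40 and the two-cell fraction, the miss probability is
`r signif(miss_probability(40, 0.25, 4), 3)` — so detection power exceeds
99.5% for both zygotic stages. The sum is evaluated exactly (depths are
small); no normal approximation is used. Expected spontaneous DNM counts
are the product of a per-nucleotide per-generation rate band and the
callable diploid site count — the latter defaults to $2 \times 2.9\,$Gb but
must be supplied deliberately for any report, since published expected-DNM
bands are typically literature values rather than reproducible products.

## What the simulator emulates — and what it does not

`trio_sim_config()` defines the whole synthetic study; every stochastic
step draws from a stream keyed by `(seed, purpose)`, so adding one feature
never perturbs another and a fixed seed gives byte-identical outputs.

Emulated, with defaults chosen for the validation scenario:

* a uniform-random reference (1 Mb over 2 chromosomes) carrying the
  protospacer+NGG on-target cassette and one planted off-target site per
  requested mismatch count, on random strands;
* independent parental variants at $10^{-3}$/bp (30% homozygous), Mendelian
  inheritance with seeded allele draws, and half of parental variants
  entered into the known-variant database;
* 20 true DNMs per offspring at allele fractions 0.5 or 0.25, planted at
  positions free of parental variants, masks and planted features;
* 200 parental-allele violation artifacts per offspring (the dominant
  real-data noise class; a small fraction built on a het parent instead of
  opposite homozygotes) and 5 sibling-shared novel-allele artifacts, which
  only cross filtering can remove;
* four caller views sharing one sequencing experiment: depth Poisson around
  46 (the study-scale median; `depth_fixed` pins it), allelic depths
  binomial at the true allele fraction, genotype quality two-point
  (99/10), per-caller dropout and false calls, and an annotation-error knob
  that makes a configurable fraction of sites violate QD/MQ/GQ/strand
  thresholds;
* masks: random mappability/repeat components hitting a target fraction
  (5%) plus every homopolymer run ≥ 10 bp as low-complexity;
* trio SV sets for two callers with jittered coordinates, spanning
  inherited, sibling-shared, known-database, optional de novo and
  caller-specific classes.

A planted DNM is emitted as a het genotype only when its sampled alt reads
reach `ceiling(0.1 × DP)` — the same rule the power model describes — and
the truth table records which DNMs were detectable in this sense. Recall is
reported against both all planted DNMs and the detectable subset; no
pipeline can recover a mutation the reads do not support.

Two generator conventions matter for interpreting "error-free" runs. First,
strand counts are deterministically balanced (floor/ceiling split of the
summed allelic depths): a binomial split would let Fisher's exact test
reject a few percent of genuinely unbiased sites, i.e. the clean regime
would not be clean. Strand skew is injected explicitly through the
annotation-error knob. Second, caller false calls avoid positions used by
the truth set, so false-positive keys are caller-specific by construction.

Not emulated: read-level sequence simulation (no FASTQs, no alignment, no
base-error model), genotype-likelihood models (GQ is a two-point stand-in
sufficient to exercise thresholds), linked variation or population
structure, and mosaicism beyond a single fraction per DNM. Passing
end-to-end tests therefore demonstrates that the *filtering logic* is
correct and internally consistent — not that the thresholds are optimal for
any particular sequencing platform.

## Numerical and design choices

* Coordinates are 0-based half-open internally; 1-based VCF positions are
  converted at the io boundary.
* Multi-allelic records are split per ALT on read, with AD collapsed to
  (ref, that alt); genotype alleles are stored as bases, not indices, so
  allele identity survives the split and the Mendelian logic never
  confuses alleles.
* All threshold comparisons are strict; boundary values fail (except the
  allele-balance floor discussed above).
* The binomial allele-balance test is two-sided and exact; the strand test
  is Fisher's exact test.
* Ties in SV consensus are resolved greedily by the best minimum overlap
  fraction; each record matches at most once.
* The problem sizes used by the test-suite and the acceptance script — a
  1 Mb genome, 20–250 planted DNMs, 500 Monte-Carlo mosaic draws — were
  chosen as the smallest sizes at which every statistical check has
  non-trivial resolution (e.g. the 95% binomial band around 99.5% power is
  [98.8%, 100%] at 500 draws).

## Known limitations

* The detector front end is a genotype-configuration rule, not a trio
  likelihood model; on real data a likelihood caller may rank candidates
  differently even though the post-cascade set is filter-dominated.
* "Shared between offspring" uses exact variant-key equality; near-duplicate
  sharing (±1 bp) is not detected.
* The on-target ratio operates on simplified read records (alignment span
  plus deletion spans); it does not parse CIGAR strings or BAM files.
* Off-target scanning is ungapped; RNA/DNA bulges and activity scores are
  out of scope.
* The strand-bias inputs of real callers differ in INFO-field naming; the
  `dialect` argument of `read_vcf()` is the hook for such mappings, with a
  single generic dialect implemented.
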