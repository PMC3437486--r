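---
title: "From transcript assembly to markers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From transcript assembly to markers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tusmarkers)
```

`tusmarkers` covers the computational half of a de-novo transcriptome
project that starts *after* assembly: a set of tentative unique sequences
(TUSs) is cleaned and classified, mined for simple sequence repeats,
profiled for expression with short sequence tags from two genotypes,
screened for inter-genotype SNPs, and converted into three families of
PCR markers (SSR, intron-spanning, conserved-ortholog). This vignette
explains each model and rule, the tunable parameters and their defaults,
and the design choices made where the conventions of the field leave the
question open. Assembly itself is out of scope: the package consumes an
assembler's contig FASTA and membership table (the upstream CAP3 preset
`-p 95 -o 50 -g 3 -y 50 -t 1000` is recorded here purely as
configuration documentation), and it consumes spliced aligner output as
GFF3 rather than running an aligner.

## Cleanup and TUS classification

Poly-A tails (and their reverse-complement poly-T heads) are trimmed when
a terminal run reaches `min_run = 8` nt. A run may absorb occasional
sequencing errors: a non-A position is crossed only when the next 10 nt
inward contain at most `max_mismatch_per10 = 1` non-A bases. This local
density rule was chosen over a cumulative mismatch budget because a
cumulative budget accumulated over a long pure tail will happily spend
its savings chewing into genuine sequence just inside the tail. Trimming
iterates to a fixed point and is therefore idempotent. Neither threshold
comes from a published standard; both are conventional EST-cleanup values
and are exposed as arguments.

The low-complexity screen drops a sequence when any single base exceeds
`max_mono_fraction = 0.8` of its length — a deliberately blunt
homopolymer filter, matching what adapter/quality prescreens leave
behind.

A two-read contig whose per-base depth profile has zero standard
deviation (both reads span the full contig) is classified a
**high-confidence singleton**. This is the only reading of "zero read
coverage variation" under which such a contig is informatically
indistinguishable from a singleton, which is the point of the category:
it likely represents a unique gene expressed at low level. Identical
duplicate reads are not distinguished from merely coextensive ones; the
rule cannot separate them without trace-level information.

## SSR mining

Detection reports maximal perfect tandem repeats of 1–6 nt units meeting
the canonical MISA minimum repeat numbers (mono 10, di 6, tri–hexa 5; all
configurable). Two conventions deserve explanation:

* **Shortest primitive unit.** A tract like `ATATATATATAT` is reported
  once, as `(AT)6`, never additionally as `(ATAT)3`: units that are
  whole-number repetitions of a shorter unit are suppressed. Overlapping
  candidates of different unit lengths are resolved left to right
  (leftmost-maximal; at equal start the longer tract wins, then the
  shorter unit), so every reported motif set is non-overlapping.
* **No canonicalization.** `AG`, `GA`, `TC` and `CT` are reported as four
  distinct motifs, because that is how SSR surveys in this field tabulate
  them; `canonical_unit()` offers rotation/reverse-complement grouping as
  an opt-in report, never as the default.

Compound SSRs are motifs separated by at most `max_interruption = 100` nt
(the MISA convention), grouped transitively; members keep their
individual counts. Class I is a total tract length of at least 20 nt —
the long-hypervariable convention — because marker programs preferentially
synthesize primers for long tracts. Marker candidates must have unit
length ≥ 2 (mono repeats are mostly 454 homopolymer artifacts), a
successful primer design, and a predicted product of at least 100 bp.
The redundancy screen drops a candidate when it hits a prior-marker
source at E ≤ 1e-5 with query coverage ≥ 30 % and identity strictly
above 90 %. PIC uses the Botstein form
`1 − Σp² − Σ_{i<j} 2 p_i² p_j²`.

The detector is property-tested against a brute-force `O(n²·6)`
enumeration oracle on sequences up to 200 nt, and against planted truth
from the simulator (recall must be exact).

## Tag expression

Tags are fixed-length (36 nt by default) reads used purely for counting.
The mapper indexes every k-mer of every TUS on both strands in a hash,
with two half-length seed tables providing one-mismatch lookup by the
pigeonhole principle; all equal-best placements are reported
(zero-mismatch placements pre-empt one-mismatch ones). Multi-mapping
policy is applied only at counting time: `unique_only` (default), `all`,
or `fractional` (1/n per placement, so fractional counts conserve the
mapped-tag total). `unique_only` is the default because heavy
multi-mapping against an EST assembly is more often assembler redundancy
than biology, and both expression and variant calling are safer ignoring
it.

Normalization is counts per million mapped tags of each library.
Fold change is `log2(cpm1/cpm2)`, defined only when both counts are
positive; TUSs seen in a single library are reported as
exclusive-expression classes instead, and the four categories
(both/exclusive×2/undetected) partition the TUS set. Fold bins split
`|log2fc|` at 1, 2, 3 and 4, with the boundary value 4 in the 3–4 bin
(the top bin is "more than four-fold", a strict bound). The R-statistic
uses the natural log (as the underlying likelihood-ratio derivation
does) while fold change uses log2 (as expression reporting does). The DE
set is `{|log2fc| ≥ 2} ∪ {R > 6}` with inclusion–exclusion accounting;
both thresholds are arguments.

Null calibration is tested empirically: with both counts Poisson at an
equal rate of 5 per million and 10⁴ replicates, the observed exceedance
`P(R > 6)` must stay below 2 % (it is ~0.1 %; `2R` is asymptotically
χ²₁, so the analytic exceedance is ≈ 5 × 10⁻⁴).

## Variant mining

"Allele frequency" is operationalized as the alternate-allele fraction
among the reads of the **non-reference genotype**, with depth measured in
that same pileup — numerator, denominator and depth filter refer to one
read set, which is the only self-consistent reading. Candidates are
emitted at positions covered in both genotypes with depth ≥ 3; the
calling filter additionally requires frequency > 0.1 and depth < 500.
All emitted positions (including sub-threshold frequencies) are binned
into the 10 × 4 frequency-by-depth classification matrix, whose cells
always sum to the binned-candidate count. The two confidence tiers
overlap by definition (frequency ≥ 0.9 & depth ≥ 3 versus
frequency > 0.60 & depth > 10), so they are reported both as a
precedence-ordered tier label and as independent flags.

Because the tag mapper is ungapped (exact or one substitution), indels
are unobservable in its alignments; the caller therefore covers
substitutions only, and the VCF writer simply accepts indel tokens if a
gapped upstream aligner supplies them. Output is VCF v4.2 (CHROM = TUS
id; INFO AF/DP/TIER), validated in tests by round-tripping through a
standard VCF parser.

## Marker design

**Introns** are genomic gaps between consecutive exon blocks of a spliced
alignment, accepted between `min_intron = 40` and `max_intron = 5000` nt.
The 5000 cap mirrors the upstream aligner configuration; the 40 floor is
this package's choice — smaller gaps are indistinguishable from alignment
indels, and genuine plant introns below ~40 nt are rare. Alignments
scoring below half the best score for the same transcript are dropped
before design, mirroring the aligner's retention rule. Transcripts whose
genomic spans are separated by ≤ 1000 uncovered bp are merged into one
transcribed unit (transitively; order-invariant).

**ISR primers** place the left primer entirely in the exon 5' of a
junction and the right primer entirely in the exon 3' of it, so the
transcript product spans exactly that junction and
`product_genomic = product_transcript + intron length` — an identity the
tests verify exactly. **The primer engine** is a deterministic exhaustive
search; thermodynamics use the SantaLucia unified nearest-neighbor
parameters with the `0.368·(N−1)·ln[Na⁺]` entropic salt correction at
50 mM Na⁺ and a CT/4 term at 50 nM total oligo. Frozen reference Tm
values from an independent implementation pin the model in the tests.
Ranking is lexicographic — summed |Tm − 60|, then |product − optimum|,
then leftmost — so results are reproducible to the base pair. ISR
products default to 80–400 transcript bp; SSR products to 100–500 bp.

**COS cascade.** Stage 1 keeps queries with a hit at E ≤ 1e-30 in every
one of six species; stage 2 requires the normalized best-hit annotation
(case-folded, punctuation-stripped, isoform/fragment suffixes removed) to
be identical across all six; stage 3 removes paralog-flagged queries;
stage 4 removes queries matching a prior COS set at E ≤ 1e-5 with
coverage ≥ 25 %. The paralog flag is this package's interpretation, since
marker surveys rarely print one: a query is flagged iff in any single
species it has two or more distinct subjects at E ≤ 1e-30 with bitscore
within 90 % of that species' best — i.e. the species cannot tell two
loci apart. Stage-2 comparison uses best hits only. Stage counts are
monotone non-increasing by construction.

## The synthetic-data generator

`sim_config()` fixes the study conditions: 500 TUSs with log-normal
lengths around 460 nt (bounds 150–1200), planted `(AG)8`, `(TTC)7` and
`(A)12` repeats in distinct hosts with non-repeat guard bases (so the
planted tract is exactly the truth-table tract), 20 % poly-A tails of
12–25 nt, 30 genes with 2–4 exons and introns of 80–2000 nt on a toy
genome plus 5 intronless pairs placed within 1000 bp to exercise the
merge rule, 60 homozygous substitutions distinguishing genotype 2,
log-normal abundances (meanlog 3, sdlog 1.2), ten planted genes at
log2fc +3 and ten at −3 split symmetrically between libraries, 10⁵ tags
of 36 nt per library, and a 1 % uniform per-base substitution error.
These sizes keep every stage in seconds-to-minutes on one CPU while
giving planted variants a median pileup depth near 15×, enough to
exercise the depth tiers on both sides.

What the generator does *not* emulate — and hence what passing tests do
not establish about field data: 454 homopolymer miscalls and
assembler-induced redundancy (the main source of real multi-mapping),
quality-score-dependent errors (tags are modeled as pre-filtered),
imperfect/interrupted repeats, heterozygous variant frequencies between
the planted extremes, alternative splicing, and cross-contamination
between libraries. The ortholog tables are constructed hit tables with
designed stage outcomes, not sequence-derived alignments.

Every simulate function derives its RNG stream from the config seed, so
identical configs give byte-identical outputs; the truth table is closed
over the emitted files (every planted feature is in the output and vice
versa), which the tests assert directly.

## Numerical and degenerate-input conventions

All coordinates are 1-based inclusive everywhere, including hit tables.
Ambiguity codes beyond N are rejected at input rather than remapped,
because the repeat scan and k-mer index assume a five-letter alphabet.
The R-statistic is clamped at zero against floating-point droop and is an
error when both counts are zero (the record is classed `undetected`
instead). `pick_primers` failures carry reason codes
(`no_feasible_left/right/pair`) rather than empty results. Ties in
primer ranking, SSR overlap resolution and tier precedence are all broken
deterministically as described above, so no output depends on iteration
order or hashing.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the full toy pipeline at
the default conditions (500 TUSs, 2 × 10⁵ tags), the SSR oracle
comparison on sequences ≤ 200 nt, the null calibration at 10⁴
replicates, and the published-scale accounting tables as shipped under
`inst/extdata/` (an SSR survey of 103 215 sequences, a 21 620-cell SNP
classification matrix, a 638-family ortholog cascade). Accounting totals
are always recomputed from components, never copied.
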