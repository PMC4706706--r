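---
title: "Methods: variant normalization, reversible sortable keys, and cohort analyses"
author: "rvstore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant normalization, reversible sortable keys, and cohort analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvstore)
```

`rvstore` is a small-variant registry: it canonicalizes SNVs, MNVs and
indels against a reference genome, identifies each by a reversible,
byte-sortable base-64 key, accumulates per-study evidence, and runs the
cohort analyses a curated variant resource is used for. This vignette
documents the methods, the parameters that matter, the numerical choices,
and what the test evidence does and does not show.

## Canonical representation

Two spellings of the same edit — right-shifted indels in repeat tracts,
un-trimmed alleles with shared context, multi-allelic rows — must map to
one record, or the store double-counts. `leftAlign()` applies the
standard canonicalization: repeatedly trim a shared trailing base
(extending 5′ from the reference when an allele would empty), then trim
shared leading bases. The result is the unique 5′-most representation.

Conventions, chosen where the canonical form is genuinely a convention
rather than a theorem:

* **Anchor base.** Length-changing variants keep one 5′ reference base, as
  in VCF, so REF and ALT are never empty and an insertion can never share
  a key with an SNV at the same start (their allele lengths differ). Pure
  substitutions are fully trimmed.
* **Position-1 indels.** An indel whose left shift reaches position 1 with
  no 5′ base is anchored with the following (3′) base and flagged
  (`anchor = "3prime"`). This is rare and mirrors the VCF convention for
  telomeric indels.
* **Case.** Input is case-insensitive; output is upper case.
* **Multi-allelic records** are decomposed one ALT at a time before
  normalization; the store is keyed per alternate allele.

`classifyVariant()` labels trimmed pairs as SNV, MNV (equal length > 1),
INS/DEL (one allele a prefix of the other), or INSDEL otherwise.
Effective size is `|nchar(ref) − nchar(alt)|`; indels of effective size
at most 1000 bp are "small" — the store's intended domain.

The correctness argument is deliberately two-routed: the test suite
enumerates, by brute force over a reference window
(`enumerateSpellings()`, which never calls `leftAlign()`), every
(pos, ref, alt) triple that reproduces the same edited sequence, and
checks that (a) all spellings normalize to one key and (b) the normalized
form equals the enumeration's own canonical pick (minimal total allele
length, then smallest position).

## The key

The key packs (build, chromosome, start, end, alt length, alt) into a
string over 64 symbols chosen to be in strictly increasing byte order —
digits, `@`, `A`–`Z`, `_`, `a`–`z` — so byte-wise sorting of keys equals
genomic ordering, and a 7-character prefix (build + chromosome + start)
supports range scans. Positions use 5 symbols (64⁵ ≈ 1.07 × 10⁹, ample
for the largest human chromosome at ≈ 2.5 × 10⁸); the allele-length field
uses 2 symbols and therefore saturates at 4095.

The alternate allele is packed 3 nucleotides per symbol (4³ = 64),
zero-padding the final triplet; the separately stored length makes the
padding unambiguous, so packing is lossless. With the total key capped at
1000 characters, 986 payload symbols remain after the 14-character
header: alleles up to 2958 nt round-trip exactly and the key is flagged
`unique`. Three design points were open and resolved as follows:

* **Packing density.** 3 nt/symbol is the unique density for which a
  1000-character cap yields the 2958-nt uniqueness limit
  ((1000 − 14) × 3 = 2958); 2 nt/symbol would waste bits and 4 nt/symbol
  does not fit 64 symbols.
* **Key cap 1000.** Chosen as the index-key-size-style cap that
  reproduces the 2958 limit; it is a named constant, not scattered magic.
* **Build symbol.** The GRCh version number is used directly as an
  alphabet index (36/37/38); reversible and readable.

Non-ACGT alleles (N, IUPAC codes, symbolic ALTs) are rejected by
`packAllele()`; `encodeKey()` then emits a key with an empty payload and
`unique = FALSE`, and such records — like truncated oversized insertions —
are retrieved by chromosomal location plus alternate allele. Two
different oversized insertions at one locus may share key text; the
registry therefore identifies records by the (build, chrom, start, end,
alt) tuple and treats the key as a unique index only where the unique
flag holds, raising a collision error if a unique key would ever alias
two alleles.

Because R's string collation is locale-dependent while key order is
byte-defined, sorting and range tests go through `keyOrder()` /
`keysInRange()` (radix/byte comparisons), never `<` on characters.

## Registry semantics

Ingestion is staged: a batch is normalized, deduplicated (pass flags
OR-ed across duplicate records of one variant), partitioned into known
and novel against the production table, then committed. Novel variants
become queryable immediately with their fast-to-compute fields (type,
effective size, key); re-registration is a no-op for summary rows, so
store content is ingestion-order invariant — a property the suite checks
by permuting batch orders.

A variant *passes* for a study if at least one contributing record passed
that study's filters (FILTER `PASS` or `.`; `.` is treated as pass and
logged, a documented reading of the VCF ambiguity). `noveltyReport()`
counts per study the distinct variants, those observed in no other study,
and those passing. Annotation tables (impact, prediction, phenotype,
region) attach by key or by normalized coordinates; rows for unseen
variants create annotation-only records with empty sources, so clinical
catalogues can be loaded before any cohort observes the variant.

The backing store is an environment of data.frames inside an S4 object
with TSV persistence (`writeRegistry()` / `readRegistry()`) — an
embeddable, dependency-free choice; the public surface would not change
if a relational backend were substituted.

## Frequencies and cohort analyses

`maxEthnicityAF()` returns, per variant, the maximum AF over every
(study, subpopulation) pair in a cohort set; studies without a breakdown
contribute their overall AF (stored as the `ALL` pseudo-subpopulation,
which never exceeds the per-subpopulation maximum since it is their
weighted mean). Unobserved variants get 0, which is also its own
frequency bin: the bins `0 | 0–0.001 | 0.001–0.005 | 0.005–0.01 |
0.01–0.05 | 0.05–0.1 | 0.1–0.5 | ≥0.5` are non-cumulative and exclude
their upper boundary (0.001 belongs to `0.001–0.005`; 0.5 to `≥0.5`).

`clinicalBinTable()` excludes, per source, variants asserted with
contradicting pathogenicities. The rule had to be fixed by design: a
variant is contradictory for a source iff it carries at least one of
{pathogenic, likely_pathogenic} and at least one of
{benign, likely_benign} from that source; any other mixture is kept under
its most severe label (severity order `significanceLevels()`). Cell
values are percentages of the source's retained total, so each source's
row block sums to 100 within rounding; percentages print at two decimals.

`flagPathogenicCommon()` applies the population-frequency sanity check:
an allele common in healthy populations is unlikely to be highly
penetrant pathogenic. The default threshold is 1% maximum AF in any
population, with 0.1% as the documented stricter alternative for
autosomal dominant disorders; thresholds are parameters, and a stricter
threshold provably returns a superset (tested).

`exclusiveToCohort()` returns variants with carriers (aggregate AC > 0)
in the disease cohort and zero alternate alleles in every background
cohort, with optional impact and pass-flag filters. The operation is
antitone in the background list (adding a background never adds a
variant), which the suite asserts. Carrier logic is allele-count based;
genotype-level carrier reasoning is out of scope unless genotype counts
are imported.

`compareCohorts()` screens for AF differences. The significance test was
an open choice; a two-sided Fisher exact test on the aggregated 2 × 2
allele-count table `[(AC₁, AN₁ − AC₁), (AC₂, AN₂ − AC₂)]` with
Benjamini–Hochberg adjustment is the standard screen and exact at the
small counts that dominate rare-variant work. The p-value is computed by
an internal vectorized routine (`exactTest2x2()`) that sums the
conditional hypergeometric probabilities of all tables no more probable
than the observed one, with the conventional 1 × 10⁻⁷ relative tie
tolerance — the same definition `stats::fisher.test()` implements, to
which the suite ties it at 10⁻¹² on random tables, while an independent
binomial-coefficient enumeration oracle covers every table with margins
up to 50 exhaustively. Vectorization is what makes that exhaustive sweep
(1.76 million tables) affordable. When the observed table is modal the
p-value is returned as exactly 1 rather than 1 − ε from floating-point
summation. Variants absent from one cohort are tested as 0 carriers out
of that cohort's maximum observed allele number — the natural reading of
"not seen in this many alleles"; cohorts that carry AF without allele
counts cannot be tested and are reported as flagged AF deltas instead.

## The simulator: what it emulates and what it does not

`simDesign()` draws everything once per seed — reference contigs, a pool
of variant sites, study membership, allele counts, pass flags, emitted
spellings, clinical assertions — and stores the realized truth in the
design object; the file writers are deterministic renderings, so
regeneration is bit-reproducible (tested byte-for-byte).

Default study conditions, chosen once as a realistic desk-scale cohort
structure: two 100-kb contigs at GC 0.41; four studies — three healthy
(2500 samples with EUR/AFR/EAS subpopulations, 3000 with EA/AA, 400
without breakdown) and one 150-sample disease cohort; 220 variant sites
(~60% SNV, ~34% indel, ~6% MNV) plus 12 assertion-only variants and 2
oversized insertions; an AF spectrum of 15% common (0.05–0.5), 25%
low-frequency (0.005–0.05), 45% rare (0.0005–0.005), 15%
single-study-private; 10 disease-private plants; 4 pathogenic-common
plants (AF 0.02–0.2); 4 contradictory assertion pairs; 30% denormalized
spellings; 10% filter failures. AC is drawn per subpopulation and AF is
stored as exactly AC/AN. Indel sites are embedded in planted homopolymer
or dinucleotide tracts (6–10 units) so left-alignment is actually
exercised; canonical truth for every site comes from the enumeration
oracle, not from `leftAlign()`.

What passing tests on these data do **not** show: robustness to malformed
or exotic VCF (the generator writes clean 4.2), linkage structure or
genotype-level effects (the simulator draws allele counts, not genomes),
realistic site-frequency spectra or mutation-rate heterogeneity, build
liftover, structural variants, and scale (the store is exercised at
hundreds, not hundreds of millions, of variants).

## Numerical and degenerate-input choices

* Key comparisons are byte-wise; locale never enters.
* Positions decode to R integers (64⁵ < 2³¹).
* `binAF()` is total on [0, 1]; values outside error.
* Empty inputs (header-only VCF, empty staging batch, empty selection)
  produce empty, correctly typed results, not errors.
* Reference mismatches and out-of-bounds coordinates are hard errors at
  normalization; annotation rows with mismatched ref are rejected.
* Duplicate frequency rows for one (variant, study, subpopulation) keep
  the first occurrence; pass flags OR.

## Problem sizes used by the test suite

Round-trip and sort-congruence properties run at 10⁴ random variants
(alt lengths uniform up to 2958 nt for the round trip); normalization
convergence at ~10³ planted edits with full spelling enumeration; the
exact-test oracle sweep at all 1 755 625 tables with margins ≤ 50; the
full-pipeline truth-recovery at the default 240-site design, with an
88-variant disease-private design for the exclusivity count. These sizes
were chosen as the package's documented property-testing scale.

## Known limitations

* One reference build per store; cross-build lookup tables are imported
  metadata, not computed liftover.
* The allele-count exact test treats cohorts as independent allele pools;
  overlapping samples between studies would inflate counts.
* Non-ACGT alleles are storable but never key-unique; they rely on
  location + allele access.
* The in-memory backing store targets embeddable, desk-scale use; very
  large stores would need a database backend behind the same surface.
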