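# rvstore — an embeddable reference variant store

Large resequencing efforts keep re-annotating the same small variants: every
new call set is run through the same normalizers, annotators and frequency
lookups even though most of its variants were seen before. `rvstore` is an
embeddable R implementation of the infrastructure that removes that
redundancy: variants are normalized once, given a globally unique,
reversible, sortable identifier, and registered in a store that accumulates
per-study evidence (sources, quality flags, subpopulation allele
frequencies) and imported annotations. On top of the store it implements
the cohort analyses such a resource exists for — frequency cross-checks of
clinically asserted variants, discovery of disease-exclusive variants, and
exact-test screening for allele-frequency differences between cohorts.

It is aimed at statistical geneticists and bioinformatics engineers who
need variant bookkeeping across studies without standing up a database
server: the store is an in-memory S4 object with plain-text persistence.

## The variant key

Each left-aligned variant gets a fixed-layout string key over a 64-symbol
alphabet in strictly increasing byte order (digits, `@`, upper case, `_`,
lower case), so byte-wise string sort equals genomic sort:

| chars | content |
|---|---|
| 1 | genome build (GRCh version as alphabet index) |
| 2 | chromosome code (1–22, X = 23, Y = 24, MT = 25) |
| 3–7 | start position, base 64, big-endian |
| 8–12 | end position (`start + nchar(ref) − 1`) |
| 13–14 | alternate-allele length (up to 64² − 1 = 4095) |
| 15– | packed alternate allele, 3 nucleotides per symbol (4³ = 64) |

Keys are capped at 1000 characters, so alleles up to
(1000 − 14) × 3 = **2958** nucleotides are encoded losslessly (`unique =
TRUE`); longer or non-ACGT alleles get a truncated/empty payload, are
flagged non-unique, and are retrieved by location + allele instead. Key
prefixes (`rangePrefix()`) support byte-wise range scans by build,
chromosome and start.

Variants are canonicalized before keying: redundant shared context is
trimmed, indels are shifted to their 5′-most equivalent position, and
length-changing variants keep one 5′ anchor base (VCF convention), so every
spelling of an edit maps to one key.

## Analyses

* `maxEthnicityAF()` / `binAF()` / `clinicalBinTable()` — maximum
  ethnicity-specific allele frequency across cohorts, and the percentage
  table of clinically asserted variants per significance label across
  non-cumulative AF bins `0 | 0–0.001 | … | ≥0.5` (upper bounds excluded;
  contradictory assertions within a source excluded).
* `flagPathogenicCommon()` — asserted variants whose maximum AF in healthy
  populations reaches a threshold (default 1%; 0.1% as the stricter
  alternative for autosomal dominant disorders).
* `exclusiveToCohort()` — variants with carriers only in a disease cohort
  and zero alternate alleles in every background cohort.
* `compareCohorts()` — per-variant two-sided Fisher exact test on
  aggregated allele counts with Benjamini–Hochberg adjustment.

A deterministic simulator (`simDesign()`, `simulateAll()`) generates
reference FASTA, multi-study VCFs with subpopulation `AC/AN/AF` INFO
fields, FILTER failures, denormalized spellings, and clinical assertion
tables with planted contradictions — so the entire pipeline is testable
offline, against the generator's own truth tables.

## Worked example

```r
library(rvstore)

design <- simDesign(seed = 42)          # 240 variant sites, 4 studies
reg <- ingestDesign(design, tempfile()) # render files, ingest, annotate
reg
#> VariantRegistry (GRCh37)
#>   variants:  240
#>   studies:   diseaseD, healthyA, healthyB, healthyC
#>   freq rows: 937; annotation rows: 44

noveltyReport(reg)
#>      study variants unique_to_study passed
#> 1 diseaseD       60              24     53
#> 2 healthyA      126              44    110
#> 3 healthyB       98              33     93
#> 4 healthyC       79              26     69

k <- encodeKey(37, 1, 100, 100, "T"); k$text
#> [1] "_10001Z0001Z01k"
decodeKey(k$text)$alt
#> [1] "T"

flags <- flagPathogenicCommon(reg, c("healthyA", "healthyB", "healthyC"))
head(flags, 3)
#>               key source significance  max_af
#> 1 _1004uN004uN01V clindb  risk_factor 0.31800
#> 2 _1003yM003yO01V clindb   pathogenic 0.19625
#> 3 _1004400044001V clindb   pathogenic 0.17625
```

`noveltyReport()` counts, per study, the distinct variants observed, the
variants seen in no other study, and the variants whose quality (pass)
flag is set. The key `_10001Z0001Z01k` spells build 37 (`_`), chromosome 1
(`1`), start and end 100 (`0001Z`), allele length 1 (`01`), and the packed
allele `T` (`k`). `flagPathogenicCommon()` lists asserted variants whose
maximum healthy-population AF is at least 1% — candidates for curation
review.

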