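# A small handcrafted study VCF: multi-allelic record, a filtered record,
# an AF-only record, and a denormalized deletion spelling.

vcf_fixture <- function(dir = tempfile("vcfio")) {
  dir.create(dir, showWarnings = FALSE)
  ctg <- paste0("TTTTT", "GCACACACG", strrep("A", 26), "GATTACAGGT",
                strrep("C", 10), "GTAGCTAGCT")
  fa <- file.path(dir, "ref.fa")
  writeLines(c(">1", ctg), fa)
  vcf <- file.path(dir, "study.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=1,length=", nchar(ctg), ">"),
    '##FILTER=<ID=q10,Description="Low quality">',
    '##INFO=<ID=AC,Number=A,Type=Integer,Description="ac">',
    '##INFO=<ID=AN,Number=1,Type=Integer,Description="an">',
    '##INFO=<ID=AF,Number=A,Type=Float,Description="af">',
    '##INFO=<ID=AC_EUR,Number=A,Type=Integer,Description="ac eur">',
    '##INFO=<ID=AN_EUR,Number=1,Type=Integer,Description="an eur">',
    '##INFO=<ID=AF_EUR,Number=A,Type=Float,Description="af eur">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    # multi-allelic SNV; per-ALT counts
    "1\t6\t.\tG\tA,T\t50\tPASS\tAC=4,2;AN=200;AF=0.02,0.01;AC_EUR=3,1;AN_EUR=100;AF_EUR=0.03,0.01",
    # filtered record
    "1\t20\t.\tA\tG\t10\tq10\tAC=1;AN=200;AF=0.005",
    # AF present, counts absent
    "1\t41\t.\tG\tC\t99\t.\tAF=0.12",
    # non-left-aligned CA deletion inside the CACACA tract (canonical: pos 6)
    "1\t10\t.\tACA\tA\t60\tPASS\tAC=7;AN=200;AF=0.035"
  ), vcf)
  list(dir = dir, fa = fa, vcf = vcf, ctg = ctg)
}

test_that("study VCFs decompose per ALT with per-subpopulation counts", {
  fx <- vcf_fixture()
  got <- readStudyVcf(fx$vcf, "s1", subpopFieldMap("EUR"))
  expect_identical(nrow(got$calls), 5L)          # 4 records, one with 2 ALTs
  ma <- got$calls[got$calls$pos == 6, ]
  expect_setequal(ma$alt, c("A", "T"))
  expect_false(got$calls$passed[got$calls$pos == 20])
  expect_true(all(got$calls$passed[got$calls$pos != 20]))

  fr <- got$freqs
  a6 <- fr[fr$rid == ma$rid[ma$alt == "A"], ]
  expect_identical(a6$AC[a6$subpop == "ALL"], 4)
  expect_identical(a6$AN[a6$subpop == "ALL"], 200)
  expect_identical(a6$AF[a6$subpop == "ALL"], 4 / 200)
  expect_identical(a6$AC[a6$subpop == "EUR"], 3)
  # AF-only record: AN stays NA, AF kept as printed
  rid31 <- got$calls$rid[got$calls$pos == 41]
  expect_true(is.na(fr$AN[fr$rid == rid31 & fr$subpop == "ALL"]))
  expect_identical(fr$AF[fr$rid == rid31 & fr$subpop == "ALL"], 0.12)
})

test_that("missing subpopulation INFO keys warn but retain observations", {
  fx <- vcf_fixture()
  expect_warning(got <- readStudyVcf(fx$vcf, "s1", subpopFieldMap(c("EUR", "AFR"))),
                 "AFR")
  expect_identical(nrow(got$calls), 5L)
  expect_false("AFR" %in% got$freqs$subpop)
})

test_that("key annotation preserves everything else byte-for-byte", {
  fx <- vcf_fixture()
  reference <- loadReference(fx$fa)
  out <- file.path(fx$dir, "keyed.vcf")
  n <- writeKeyedVcf(fx$vcf, out, reference)
  expect_identical(n, 4L)

  orig <- readLines(fx$vcf)
  keyed <- readLines(out)
  expect_identical(length(keyed), length(orig) + 1L)
  # header: one added line, others unchanged and in order
  expect_identical(setdiff(keyed[startsWith(keyed, "#")],
                           orig[startsWith(orig, "#")]),
                   grep("RVSKEY", keyed, value = TRUE, fixed = TRUE)[1])
  ob <- orig[!startsWith(orig, "#")]
  kb <- keyed[!startsWith(keyed, "#")]
  for (i in seq_along(ob)) {
    fo <- strsplit(ob[i], "\t")[[1]]
    fk <- strsplit(kb[i], "\t")[[1]]
    expect_identical(fk[-8], fo[-8])
    expect_identical(fk[8], paste0(fo[8], ";",
                                   regmatches(fk[8],
                                              regexpr("RVSKEY=[^;]*", fk[8]))))
  }
  # idempotence: annotating again changes nothing
  out2 <- file.path(fx$dir, "keyed2.vcf")
  writeKeyedVcf(out, out2, reference)
  expect_identical(readLines(out2), keyed)

  # every emitted key decodes to the record's normalized coordinates
  for (i in seq_along(kb)) {
    f <- strsplit(kb[i], "\t")[[1]]
    keys <- strsplit(sub(".*RVSKEY=([^;]*).*", "\\1", f[8]), ",")[[1]]
    alts <- strsplit(f[5], ",")[[1]]
    for (j in seq_along(alts)) {
      norm <- leftAlign(f[1], as.integer(f[2]), f[4], alts[j], reference)
      d <- decodeKey(keys[j])
      expect_identical(d$start, norm$start)
      expect_identical(d$alt, norm$alt)
    }
  }
  # the denormalized deletion carries the canonical (left-shifted) key
  del <- strsplit(kb[4], "\t")[[1]]
  dk <- decodeKey(sub(".*RVSKEY=([^;]*).*", "\\1", del[8]))
  expect_identical(dk$start, 6L)
})

test_that("a header-only VCF annotates zero records", {
  dir <- tempfile("empty")
  dir.create(dir)
  vcf <- file.path(dir, "e.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=1,length=100>",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t")), vcf)
  writeLines(c(">1", strrep("A", 100)), file.path(dir, "r.fa"))
  n <- writeKeyedVcf(vcf, file.path(dir, "out.vcf"),
                     loadReference(file.path(dir, "r.fa")))
  expect_identical(n, 0L)
  got <- readStudyVcf(vcf, "s")
  expect_identical(nrow(got$calls), 0L)
})

test_that("exports write stable TSV and schema-stable JSON", {
  fx <- vcf_fixture()
  reference <- loadReference(fx$fa)
  reg <- newRegistry()
  ingestStudy(reg, fx$vcf, "s1", reference, subpopFieldMap("EUR"))

  tsv <- file.path(fx$dir, "out.tsv")
  n <- exportRecords(reg, tsv, format = "tsv")
  expect_identical(n, 5L)
  tab <- read.delim(tsv)
  expect_identical(names(tab)[1:8],
                   c("key", "chrom", "start", "end", "ref", "alt", "type",
                     "effective_size"))
  expect_identical(nrow(tab), 5L)
  expect_true(all(tab$sources == "s1"))

  js <- file.path(fx$dir, "out.json")
  exportRecords(reg, js, format = "json")
  got <- jsonlite::read_json(js, simplifyVector = FALSE)
  expect_identical(got$schema, "rvstore-export-1")
  expect_length(got$records, 5L)
  r1 <- got$records[[1]]
  expect_setequal(names(r1), c("key", "variant", "sources", "frequencies",
                               "annotations"))
  expect_identical(queryByKey(reg, r1$key)$alt, r1$variant$alt)

  # empty selection: header-only TSV
  exportRecords(reg, tsv, keys = character(0), format = "tsv")
  expect_identical(nrow(read.delim(tsv)), 0L)
})
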