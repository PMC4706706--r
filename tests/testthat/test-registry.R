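# Staging -> production workflow on small constructed batches plus the
# cached simulated cohort.

tiny_ref <- c("1" = paste0("T", paste(rep(c("A", "C", "G", "T"), 250),
                                      collapse = "")))

make_norm <- function(n, offset = 0, reference = tiny_ref) {
  raw <- data.frame(chrom = rep("1", n),
                    pos = 2 + 4 * (seq_len(n) - 1 + offset),
                    stringsAsFactors = FALSE)
  if (n == 0L) {
    raw$ref <- character(0)
    raw$alt <- character(0)
    raw$rid <- integer(0)
    return(normalizeVariants(raw, reference))
  }
  raw$ref <- substr(reference[["1"]], raw$pos, raw$pos)
  raw$alt <- c("A", "C", "G", "T")[match(raw$ref, c("C", "G", "T", "A"))]
  raw$rid <- seq_len(n)
  normalizeVariants(raw, reference)
}

test_that("staging partitions into known and novel; registration attaches sources", {
  reg <- newRegistry()
  norm <- make_norm(30)
  b1 <- stageVariants(reg, norm, "studyA")
  expect_true(all(b1$novel))
  counts <- registerBatch(reg, b1)
  expect_identical(unname(counts["novel_registered"]), 30L)
  expect_identical(length(reg), 30L)

  # same study again: nothing novel, registration is a summary no-op
  b2 <- stageVariants(reg, norm, "studyA")
  expect_identical(sum(b2$novel), 0L)
  registerBatch(reg, b2)
  expect_identical(length(reg), 30L)

  # second study sharing 10 of 30 variants: 20 novel
  norm_b <- make_norm(30, offset = 20)
  b3 <- stageVariants(reg, norm_b, "studyB")
  expect_identical(sum(b3$novel), 20L)
  registerBatch(reg, b3)
  expect_identical(length(reg), 50L)

  # shared variants: one summary row, two source rows
  src <- registrySources(reg)
  shared <- names(which(table(src$vid) == 2L))
  expect_length(shared, 10L)

  # empty batch
  b4 <- stageVariants(reg, make_norm(0), "studyC")
  expect_length(b4$novel, 0L)
})

test_that("novelty report counts unique-to-study and passed variants", {
  reg <- newRegistry()
  n1 <- make_norm(12)
  n1$passed <- rep(c(TRUE, FALSE), 6)           # 6 fail all filters
  registerBatch(reg, stageVariants(reg, n1, "only"))
  rep1 <- noveltyReport(reg)
  expect_identical(rep1$variants, 12L)
  expect_identical(rep1$unique_to_study, 12L)   # single-study store
  expect_identical(rep1$passed, 6L)

  registerBatch(reg, stageVariants(reg, make_norm(12, offset = 6), "other"))
  rep2 <- noveltyReport(reg)
  expect_identical(rep2$unique_to_study[rep2$study == "only"], 6L)
  expect_identical(rep2$unique_to_study[rep2$study == "other"], 6L)
})

test_that("store content is ingestion-order invariant (conservation)", {
  batches <- list(a = make_norm(15), b = make_norm(15, offset = 7),
                  c = make_norm(10, offset = 12))
  orders <- list(c("a", "b", "c"), c("c", "a", "b"), c("b", "c", "a"))
  stores <- lapply(orders, function(o) {
    reg <- newRegistry()
    novel <- 0L
    for (nm in o)
      novel <- novel + registerBatch(
        reg, stageVariants(reg, batches[[nm]], nm))["novel_registered"]
    list(reg = reg, novel = unname(novel))
  })
  n_distinct <- length(unique(unlist(lapply(batches, function(b)
    paste(b$start, b$alt)))))
  for (s in stores) expect_identical(s$novel, n_distinct)
  sum_of <- function(s) {
    x <- registrySummary(s$reg)
    x[order(x$vid), c("vid", "key", "vtype")]
  }
  expect_equal(sum_of(stores[[1]]), sum_of(stores[[2]]),
               ignore_attr = TRUE)
  expect_equal(sum_of(stores[[1]]), sum_of(stores[[3]]),
               ignore_attr = TRUE)
})

test_that("oversized insertions sharing a truncated key are both retained", {
  reg <- newRegistry()
  base <- strrep("ACG", 1000)                   # 3000 nt, same packed prefix
  ins1 <- paste0("T", base, "AAAA")
  ins2 <- paste0("T", base, "CCCC")
  norm <- data.frame(
    build_code = 37L, chrom = "1", chrom_code = 1L, start = 1L, end = 1L,
    ref = "T", alt = c(ins1, ins2), vtype = "INS",
    effective_size = nchar(base) + 4L, anchor = "5prime",
    key = c(encodeKey(37, 1, 1, 1, ins1)$text,
            encodeKey(37, 1, 1, 1, ins2)$text),
    stringsAsFactors = FALSE)
  expect_identical(norm$key[1], norm$key[2])    # truncated to same text
  registerBatch(reg, stageVariants(reg, norm, "s"))
  expect_identical(length(reg), 2L)
  hits <- queryByKey(reg, norm$key[1])
  expect_identical(nrow(hits), 2L)              # disambiguated by allele
  expect_setequal(hits$alt, c(ins1, ins2))
  expect_false(any(hits$unique_key))
})

test_that("a unique key never silently points at two different alleles", {
  reg <- newRegistry()
  norm <- make_norm(1)
  registerBatch(reg, stageVariants(reg, norm, "s"))
  evil <- norm
  evil$alt <- "TTTT"                            # forged: same key, new allele
  expect_error(registerBatch(reg, stageVariants(reg, evil, "s2")),
               "key collision")
})

test_that("annotation import attaches, creates annotation-only records, and is idempotent", {
  reg <- newRegistry()
  registerBatch(reg, stageVariants(reg, make_norm(5), "s"))
  seen <- registrySummary(reg)

  tab <- data.frame(chrom = "1", pos = c(seen$start[1], 903),
                    ref = c(seen$ref[1], substr(tiny_ref[["1"]], 903, 903)),
                    alt = c(seen$alt[1], "A"),
                    source = "clin", label = c("pathogenic", "benign"),
                    stringsAsFactors = FALSE)
  stopifnot(tab$ref[2] != "A")
  n <- importAnnotations(reg, tab, "phenotype", tiny_ref)
  expect_identical(n, 2L)
  expect_identical(length(reg), 6L)             # one annotation-only record
  orphan <- registrySummary(reg)
  orphan <- orphan[orphan$start == 903, ]
  expect_false(orphan$vid %in% registrySources(reg)$vid)

  # re-import: no duplicates
  expect_identical(importAnnotations(reg, tab, "phenotype", tiny_ref), 0L)
  expect_identical(nrow(registryAnnotations(reg)), 2L)

  # mismatched ref rejected
  bad <- tab[1, ]
  bad$ref <- "NOPE"
  expect_error(importAnnotations(reg, bad, "impact", tiny_ref),
               "reference mismatch")
})

test_that("key, location, and prefix-range queries return the same records", {
  reg <- cached_sim_registry()
  s <- registrySummary(reg)
  some <- s[s$chrom == "1", ][1:20, ]
  win <- range(some$start)
  by_range <- queryByRange(reg, "1", win[1], win[2])
  by_loc <- queryByLocation(reg, "1", win[1], win[2])
  expect_identical(by_range$vid[keyOrder(by_range$key)],
                   by_loc$vid[keyOrder(by_loc$key)])
  by_key <- queryByKey(reg, by_loc$key)
  expect_setequal(by_key$vid, by_loc$vid)
  # single-variant window
  one <- queryByLocation(reg, some$chrom[1], some$start[1],
                         ref = some$ref[1], alt = some$alt[1])
  expect_identical(one$vid, some$vid[1])
})

test_that("plain-text persistence round-trips the whole store", {
  reg <- newRegistry()
  registerBatch(reg, stageVariants(reg, make_norm(8), "s"))
  dir <- tempfile("store")
  writeRegistry(reg, dir)
  back <- readRegistry(dir)
  expect_identical(registrySummary(back), registrySummary(reg))
  expect_identical(registrySources(back), registrySources(reg))
  expect_identical(noveltyReport(back), noveltyReport(reg))
})
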