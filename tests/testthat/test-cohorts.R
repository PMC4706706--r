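ref_200 <- c("1" = paste0("T", strrep("ACGT", 50)))

two_cohort_registry <- function(tab) {
  # tab: pos, ac_a, an_a, ac_b, an_b; builds studies A and B (SNV A>G)
  counts <- rbind(
    data.frame(chrom = "1", pos = tab$pos, ref = "A", alt = "G",
               study = "A", AC = tab$ac_a, AN = tab$an_a,
               stringsAsFactors = FALSE),
    data.frame(chrom = "1", pos = tab$pos, ref = "A", alt = "G",
               study = "B", AC = tab$ac_b, AN = tab$an_b,
               stringsAsFactors = FALSE))
  counts <- counts[counts$AC > 0 | counts$study == "A", ]
  mini_registry(counts, ref_200)
}

test_that("the vectorized exact test equals fisher.test and the enumeration oracle", {
  set.seed(61)
  n <- 400
  an_a <- sample(2:80, n, replace = TRUE)
  an_b <- sample(2:80, n, replace = TRUE)
  ac_a <- vapply(an_a, function(m) sample(0:m, 1), numeric(1))
  ac_b <- vapply(an_b, function(m) sample(0:m, 1), numeric(1))
  p <- exactTest2x2(ac_a, an_a, ac_b, an_b)
  pf <- mapply(function(a, m, b, n2)
    stats::fisher.test(matrix(c(a, m - a, b, n2 - b), 2))$p.value,
    ac_a, an_a, ac_b, an_b)
  expect_equal(p, pf, tolerance = 1e-12)
  po <- oracle_fisher_p(ac_a, an_a, ac_b, an_b)
  expect_lt(max(abs(p - po)), 1e-12)
  # the worked example: 10/100 carriers vs 0/100
  expect_equal(exactTest2x2(10, 100, 0, 100),
               oracle_fisher_p(10, 100, 0, 100), tolerance = 1e-14)
})

test_that("identical counts give p = 1 and are never reported", {
  tab <- data.frame(pos = c(2, 6, 10), ac_a = c(5, 1, 40), an_a = 100,
                    ac_b = c(5, 1, 40), an_b = 100)
  reg <- two_cohort_registry(tab)
  a <- cohortSpec("A", "A")
  b <- cohortSpec("B", "B")
  all_res <- compareCohorts(reg, a, b, all_results = TRUE)
  expect_true(all(all_res$p == 1))
  expect_identical(nrow(compareCohorts(reg, a, b)), 0L)
})

test_that("cohort screening recovers planted differences, sorted by q", {
  set.seed(67)
  n <- 40
  tab <- data.frame(pos = 2 + 4 * (seq_len(n) - 1),
                    ac_a = rbinom(n, 200, 0.05), an_a = 200,
                    ac_b = rbinom(n, 200, 0.05), an_b = 200)
  tab$ac_a[1:3] <- c(60, 70, 80)               # strong differences
  reg <- two_cohort_registry(tab)
  res <- compareCohorts(reg, cohortSpec("A", "A"), cohortSpec("B", "B"),
                        alpha = 0.05, all_results = TRUE)
  expect_identical(nrow(res), as.integer(n))
  # p-values equal the independent oracle on the aggregated tables
  po <- oracle_fisher_p(res$ac_a, res$an_a, res$ac_b, res$an_b)
  expect_lt(max(abs(res$p - po)), 1e-12)
  hits <- compareCohorts(reg, cohortSpec("A", "A"), cohortSpec("B", "B"))
  planted <- registrySummary(reg)
  planted <- planted$key[planted$start %in% tab$pos[1:3]]
  expect_true(all(planted %in% hits$key))
  expect_false(is.unsorted(hits$q))
})

test_that("BH-adjusted discoveries control FDR on simulated null batches", {
  set.seed(71)
  n_var <- 1000; n_true <- 20; an <- 200
  fdp <- replicate(100, {
    p0 <- runif(n_var, 0.02, 0.15)
    p_a <- p0; p_a[seq_len(n_true)] <- pmin(0.6, p0[seq_len(n_true)] * 6)
    ac_a <- rbinom(n_var, an, p_a)
    ac_b <- rbinom(n_var, an, p0)
    q <- p.adjust(exactTest2x2(ac_a, an, ac_b, an), "BH")
    disc <- which(q < 0.05)
    if (length(disc) == 0) 0 else mean(disc > n_true)
  })
  # mean false-discovery proportion within binomial error of alpha
  expect_lt(mean(fdp), 0.05 + 2 * sd(fdp) / sqrt(length(fdp)) + 0.01)
})

test_that("AF-only cohorts are reported as untested AF deltas", {
  counts <- data.frame(chrom = "1", pos = c(2, 2), ref = "A", alt = "G",
                       study = c("A", "B"), AC = c(5, NA), AN = c(100, NA),
                       stringsAsFactors = FALSE)
  reg <- newRegistry()
  for (st in c("A", "B")) {
    rows <- counts[counts$study == st, ]
    rows$rid <- 1L
    norm <- normalizeVariants(rows, ref_200)
    fr <- data.frame(rid = 1L, subpop = "ALL", AC = rows$AC, AN = rows$AN,
                     AF = ifelse(is.na(rows$AN), 0.2, rows$AC / rows$AN))
    registerBatch(reg, stageVariants(reg, norm, st, fr))
  }
  expect_warning(res <- compareCohorts(reg, cohortSpec("A", "A"),
                                       cohortSpec("B", "B")),
                 "lack allele counts")
  expect_false(res$tested[1])
  expect_true(is.na(res$p[1]))
  expect_equal(res$af_b[1], 0.2)
})

test_that("pathogenic-but-common flagging honours the threshold pair", {
  ref <- ref_200
  counts <- data.frame(chrom = "1", pos = c(2, 6, 10), ref = "A",
                       alt = "G", study = "healthy1",
                       AC = c(20, 9, 300), AN = 1000,
                       stringsAsFactors = FALSE)
  reg <- mini_registry(counts, ref)
  s <- registrySummary(reg)
  anno <- data.frame(
    key = s$key[match(c(2, 6, 10), s$start)],
    source = "clin",
    label = c("pathogenic", "pathogenic", "benign"),
    stringsAsFactors = FALSE)
  importAnnotations(reg, anno, "phenotype")

  at_1pct <- flagPathogenicCommon(reg, "healthy1", threshold = 0.01)
  expect_true(s$key[s$start == 2] %in% at_1pct$key)        # AF 0.02
  expect_false(s$key[s$start == 6] %in% at_1pct$key)       # AF 0.009
  # benign variant listed under its own significance, not hidden
  expect_identical(at_1pct$significance[at_1pct$key == s$key[s$start == 10]],
                   "benign")

  at_01pct <- flagPathogenicCommon(reg, "healthy1", threshold = 0.001)
  expect_true(s$key[s$start == 6] %in% at_01pct$key)
  # stricter threshold returns a superset
  expect_true(all(at_1pct$key %in% at_01pct$key))
})

test_that("disease-exclusive discovery is exact and antitone in backgrounds", {
  d <- cached_design()
  reg <- cached_sim_registry()
  disease <- cohortSpec("disease", "diseaseD", role = "disease")
  bgs <- lapply(c("healthyA", "healthyB", "healthyC"), function(s)
    cohortSpec(s, s))

  got <- exclusiveToCohort(reg, disease, bgs)
  v <- d@variants
  want <- v$key[v$in_diseaseD & !v$in_healthyA & !v$in_healthyB &
                  !v$in_healthyC]
  expect_setequal(got, want)
  expect_true(all(v$key[v$disease_private] %in% got))

  # adding a background can only shrink the result
  for (k in 1:2) {
    fewer <- exclusiveToCohort(reg, disease, bgs[seq_len(k)])
    expect_true(all(got %in% fewer))
  }

  # pass-flag filter drops variants failing all disease-study filters
  passed <- exclusiveToCohort(reg, disease, bgs, passed_only = TRUE)
  failed_keys <- v$key[v$in_diseaseD & v$passed_diseaseD %in% FALSE]
  expect_true(all(passed %in% got))
  expect_false(any(failed_keys %in% passed))
})

test_that("a large planted private set is recovered exactly", {
  d <- cached_design(seed = 88L, n_sites = 300L, n_disease_private = 88L)
  dir <- file.path(tempdir(), "sim88")
  reg <- ingestDesign(d, dir)
  disease <- cohortSpec("disease", "diseaseD", role = "disease")
  bgs <- lapply(c("healthyA", "healthyB", "healthyC"), function(s)
    cohortSpec(s, s))
  got <- exclusiveToCohort(reg, disease, bgs)
  v <- d@variants
  want <- v$key[v$in_diseaseD & !v$in_healthyA & !v$in_healthyB &
                  !v$in_healthyC]
  expect_setequal(got, want)
  expect_identical(sum(v$disease_private), 88L)
  expect_true(all(v$key[v$disease_private] %in% got))
})
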