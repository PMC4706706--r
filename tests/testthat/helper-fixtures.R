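# Shared fixtures: cached simulation designs (building one takes seconds,
# several files reuse it), a mini-registry builder that bypasses VCF I/O,
# and an independent enumeration oracle for the exact test.

.fixture_cache <- new.env(parent = emptyenv())

cached_design <- function(seed = 42L, ...) {
  key <- paste0("design", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simDesign(seed = seed, ...)
  .fixture_cache[[key]]
}

cached_sim_registry <- function(seed = 42L) {
  key <- paste0("registry", seed)
  if (is.null(.fixture_cache[[key]])) {
    d <- cached_design(seed)
    dir <- file.path(tempdir(), paste0("simfix", seed))
    .fixture_cache[[paste0("paths", seed)]] <- simulateAll(d, dir)
    .fixture_cache[[key]] <- ingestDesign(d, dir)
  }
  .fixture_cache[[key]]
}

cached_sim_paths <- function(seed = 42L) {
  cached_sim_registry(seed)
  .fixture_cache[[paste0("paths", seed)]]
}

# truth-side novelty summary straight from the design bookkeeping
truth_novelty <- function(d) {
  studies <- sort(d@studies$study)
  m <- sapply(d@studies$study, function(st) d@variants[[paste0("in_", st)]])
  data.frame(
    study = studies,
    variants = vapply(studies, function(st) sum(m[, st]), numeric(1)),
    unique_to_study = vapply(studies, function(st)
      sum(m[, st] & rowSums(m) == 1L), numeric(1)),
    passed = vapply(studies, function(st)
      sum(d@variants[[paste0("passed_", st)]] %in% TRUE), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

# truth-side max ethnicity AF per key over the given studies
truth_max_af <- function(d, studies = d@studies$study) {
  fr <- d@freqs[d@freqs$study %in% studies, , drop = FALSE]
  keys <- d@variants$key
  mx <- tapply(fr$AF, factor(d@variants$key[fr$site], levels = keys), max)
  out <- as.numeric(mx)
  out[is.na(out)] <- 0
  names(out) <- keys
  out
}

# registry built from a plain counts table, through the public staging API
# (no VCF involved); counts: chrom,pos,ref,alt,study,AC,AN [,subpop,passed]
mini_registry <- function(counts, reference, build = 37L) {
  reg <- newRegistry(build)
  if (is.null(counts$subpop)) counts$subpop <- "ALL"
  if (is.null(counts$passed)) counts$passed <- TRUE
  for (st in unique(counts$study)) {
    rows <- counts[counts$study == st, , drop = FALSE]
    rows$rid <- seq_len(nrow(rows))
    norm <- normalizeVariants(rows, reference, build)
    fr <- data.frame(rid = rows$rid, subpop = rows$subpop,
                     AC = rows$AC, AN = rows$AN, AF = rows$AC / rows$AN,
                     stringsAsFactors = FALSE)
    registerBatch(reg, stageVariants(reg, norm, st, fr))
  }
  reg
}

# independent two-sided exact-test oracle: direct enumeration of the
# conditional distribution via binomial coefficients (lchoose), never
# touching dhyper or fisher.test
oracle_fisher_p <- function(ac_a, an_a, ac_b, an_b) {
  mapply(function(x, m, y, n2) {
    K <- x + y
    ks <- max(0, K - n2):min(K, m)
    d <- exp(lchoose(m, ks) + lchoose(n2, K - ks) - lchoose(m + n2, K))
    min(1, sum(d[d <= d[ks == x] * (1 + 1e-7)]))
  }, ac_a, an_a, ac_b, an_b)
}

random_acgt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
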