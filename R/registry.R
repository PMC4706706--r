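## The variant registry: staging -> production workflow, source tracking,
## imported annotations, novelty accounting, and queries.
##
## Backing store: data.frames held in an environment slot (so registry
## methods can update in place, the usual R idiom for a mutable store),
## with plain-text TSV persistence.  Records are identified by the tuple
## (build, chrom_code, start, end, alt); the variant key is a unique index
## for all fully-represented variants, while variants with non-unique
## (truncated) keys are disambiguated by the identity tuple, i.e. accessed
## by location and alternate allele.

setClass("VariantRegistry",
  representation(env = "environment", build_code = "integer"))

setValidity("VariantRegistry", function(object) {
  need <- c("summary", "sources", "freqs", "annot")
  if (!all(need %in% ls(object@env)))
    return("registry environment must hold summary/sources/freqs/annot tables")
  TRUE
})

empty_summary <- function() {
  data.frame(vid = character(), key = character(), unique_key = logical(),
             build_code = integer(), chrom = character(),
             chrom_code = integer(), start = integer(), end = integer(),
             ref = character(), alt = character(), vtype = character(),
             effective_size = integer(), dbsnp = character(),
             stringsAsFactors = FALSE)
}

#' Create an empty variant registry
#'
#' @param build_code Default GRCh build for the store (36, 37 or 38).
#' @return A `VariantRegistry` object.
#' @examples
#' reg <- newRegistry()
#' reg
#' @export
newRegistry <- function(build_code = 37L) {
  stopifnot(build_code %in% c(36L, 37L, 38L))
  e <- new.env(parent = emptyenv())
  e$summary <- empty_summary()
  e$sources <- data.frame(vid = character(), study = character(),
                          passed = logical(), stringsAsFactors = FALSE)
  e$freqs <- data.frame(vid = character(), key = character(),
                        study = character(), subpop = character(),
                        AC = numeric(), AN = numeric(), AF = numeric(),
                        stringsAsFactors = FALSE)
  e$annot <- data.frame(vid = character(), key = character(),
                        category = character(), source = character(),
                        label = character(), detail = character(),
                        stringsAsFactors = FALSE)
  methods::new("VariantRegistry", env = e, build_code = as.integer(build_code))
}

## internal identity tuple; the durable record id
variant_id <- function(norm) {
  paste(norm$build_code, norm$chrom_code, norm$start, norm$end, norm$alt,
        sep = ":")
}

#' @describeIn newRegistry Number of distinct registered variants.
#' @param x A `VariantRegistry`.
#' @export
setMethod("length", "VariantRegistry", function(x) nrow(x@env$summary))

#' @export
setMethod("show", "VariantRegistry", function(object) {
  s <- object@env$summary
  cat("VariantRegistry (GRCh", object@build_code, ")\n", sep = "")
  cat("  variants:  ", nrow(s), "\n", sep = "")
  cat("  studies:   ",
      paste(sort(unique(object@env$sources$study)), collapse = ", "),
      "\n", sep = "")
  cat("  freq rows: ", nrow(object@env$freqs),
      "; annotation rows: ", nrow(object@env$annot), "\n", sep = "")
})

#' Registry table accessors
#'
#' Read-only copies of the registry's backing tables: the per-variant
#' summary, the per-(variant, study) source rows with pass flags, the
#' per-(variant, study, subpopulation) allele-frequency rows, and the
#' imported annotation rows.
#'
#' @param registry A [VariantRegistry].
#' @return A data.frame.
#' @export
registrySummary <- function(registry) registry@env$summary

#' @rdname registrySummary
#' @export
registrySources <- function(registry) {
  src <- registry@env$sources
  src$key <- registry@env$summary$key[match(src$vid,
                                            registry@env$summary$vid)]
  src
}

#' @rdname registrySummary
#' @export
registryFrequencies <- function(registry) registry@env$freqs

#' @rdname registrySummary
#' @export
registryAnnotations <- function(registry) registry@env$annot

#' Stage observations and partition into known and novel
#'
#' New variant data is first loaded into a staging batch, where each
#' normalized variant is checked against the production store.  The batch
#' records which variants are already registered ("known") and which are
#' new ("novel"); [registerBatch()] then moves the batch into production.
#'
#' @param registry A [VariantRegistry].
#' @param norm Normalized variants as from [normalizeVariants()];
#'   duplicate spellings of one variant may be present and are collapsed
#'   (pass flags OR-ed; first frequency row per subpopulation kept).
#' @param study_id Study label for the batch.
#' @param freqs Optional long data.frame `rid`, `subpop`, `AC`, `AN`, `AF`
#'   (as from [readStudyVcf()]), with `rid` matching `norm$rid`.
#' @return A list of class `"StagingBatch"`: `study_id`, `variants`
#'   (deduplicated normalized rows + `vid`, `passed`), `freqs`, and logical
#'   `novel` per variant row.
#' @export
stageVariants <- function(registry, norm, study_id, freqs = NULL) {
  if (nrow(norm) == 0L) {
    return(structure(list(study_id = study_id,
                          variants = cbind(norm, vid = character(0),
                                           passed = logical(0)),
                          freqs = freqs, novel = logical(0)),
                     class = "StagingBatch"))
  }
  if (is.null(norm$passed)) norm$passed <- TRUE
  vid <- variant_id(norm)
  first <- !duplicated(vid)
  passed <- as.logical(tapply(norm$passed, factor(vid, levels = vid[first]),
                              any))
  vars <- norm[first, , drop = FALSE]
  vars$vid <- vid[first]
  vars$passed <- passed
  if (!is.null(freqs) && nrow(freqs)) {
    stopifnot(!is.null(norm$rid))
    freqs$vid <- vars$vid[match(vid[match(freqs$rid, norm$rid)], vars$vid)]
    freqs <- freqs[!is.na(freqs$vid), , drop = FALSE]
    freqs <- freqs[!duplicated(freqs[c("vid", "subpop")]), , drop = FALSE]
  }
  structure(list(study_id = study_id, variants = vars, freqs = freqs,
                 novel = !(vars$vid %in% registry@env$summary$vid)),
            class = "StagingBatch")
}

#' Register a staged batch into the production store
#'
#' Novel variants are registered immediately with their minimal
#' fast-to-compute fields (type, effective size, variant key) and are
#' visible to queries right away; a source row (with the study pass flag)
#' is attached for every variant in the batch, and per-subpopulation
#' allele frequencies are stored.  Re-registration of known variants is a
#' no-op for summary rows.  Identity is the (build, chrom, start, end,
#' alt) tuple, so two different alleles sharing a truncated non-unique key
#' are both retained rather than colliding.
#'
#' @param registry A [VariantRegistry].
#' @param batch A staging batch from [stageVariants()].
#' @return Invisibly, `c(novel_registered =, sources_attached =)`.
#' @export
registerBatch <- function(registry, batch) {
  stopifnot(inherits(batch, "StagingBatch"))
  e <- registry@env
  vars <- batch$variants
  ## recheck novelty at commit time (batch may be stale)
  novel <- !(vars$vid %in% e$summary$vid)
  if (any(novel)) {
    nv <- vars[novel, , drop = FALSE]
    uniq <- vapply(seq_len(nrow(nv)), function(i)
      encodeKey(nv$build_code[i], nv$chrom_code[i], nv$start[i], nv$end[i],
                nv$alt[i])$unique, logical(1))
    add <- data.frame(
      vid = nv$vid, key = nv$key, unique_key = uniq,
      build_code = nv$build_code, chrom = nv$chrom,
      chrom_code = nv$chrom_code, start = nv$start, end = nv$end,
      ref = nv$ref, alt = nv$alt, vtype = nv$vtype,
      effective_size = nv$effective_size,
      dbsnp = if (is.null(nv$dbsnp)) NA_character_ else nv$dbsnp,
      stringsAsFactors = FALSE)
    ## a unique key may never point at two different alleles
    clash <- add$unique_key &
      add$key %in% e$summary$key[e$summary$unique_key]
    if (any(clash))
      stop("key collision: unique key already registered for another allele")
    e$summary <- rbind(e$summary, add)
  }
  ## attach / refresh source rows (OR pass flags on re-registration)
  old <- e$sources$study == batch$study_id &
    e$sources$vid %in% vars$vid
  if (any(old)) {
    prev <- e$sources[old, , drop = FALSE]
    vars$passed <- vars$passed |
      vars$vid %in% prev$vid[prev$passed]
    e$sources <- e$sources[!old, , drop = FALSE]
  }
  e$sources <- rbind(e$sources,
                     data.frame(vid = vars$vid, study = batch$study_id,
                                passed = vars$passed,
                                stringsAsFactors = FALSE))
  if (!is.null(batch$freqs) && nrow(batch$freqs)) {
    f <- batch$freqs
    keep <- !(e$freqs$study == batch$study_id &
                paste(e$freqs$vid, e$freqs$subpop) %in%
                  paste(f$vid, f$subpop))
    e$freqs <- rbind(
      e$freqs[keep, , drop = FALSE],
      data.frame(vid = f$vid,
                 key = e$summary$key[match(f$vid, e$summary$vid)],
                 study = batch$study_id, subpop = f$subpop,
                 AC = f$AC, AN = f$AN, AF = f$AF,
                 stringsAsFactors = FALSE))
  }
  invisible(c(novel_registered = sum(novel),
              sources_attached = nrow(vars)))
}

#' Ingest a study VCF end to end
#'
#' Convenience wrapper: [readStudyVcf()] -> [normalizeVariants()] ->
#' [stageVariants()] -> [registerBatch()].
#'
#' @param registry A [VariantRegistry].
#' @param path VCF path.
#' @param study_id Study label.
#' @param reference Reference as from [loadReference()].
#' @param field_map See [readStudyVcf()].
#' @return Invisibly, the counts from [registerBatch()].
#' @export
ingestStudy <- function(registry, path, study_id, reference,
                        field_map = subpopFieldMap(character())) {
  parsed <- readStudyVcf(path, study_id, field_map)
  norm <- normalizeVariants(parsed$calls, reference, registry@build_code)
  batch <- stageVariants(registry, norm, study_id, parsed$freqs)
  registerBatch(registry, batch)
}

#' Import precomputed annotation tables
#'
#' Attaches externally computed annotation rows (functional impact,
#' deleteriousness predictions, phenotype/clinical assertions, region
#' overlaps) to registered variants.  Rows are keyed either by variant key
#' or by (chrom, pos, ref, alt), which is normalized on import.  Rows for
#' variants not yet in the store create annotation-only records (clinical
#' variants never observed in a study); rows whose ref disagrees with the
#' reference are rejected.  Re-import is idempotent.
#'
#' @param registry A [VariantRegistry].
#' @param table data.frame with either a `key` column or `chrom`, `pos`,
#'   `ref`, `alt` columns, plus `source` and `label` (and optionally
#'   `detail`).
#' @param category One of `"impact"`, `"prediction"`, `"phenotype"`,
#'   `"region"`.
#' @param reference Required when `table` is coordinate-keyed.
#' @return Invisibly, the number of annotation rows attached.
#' @export
importAnnotations <- function(registry, table, category = c("phenotype",
                              "impact", "prediction", "region"),
                              reference = NULL) {
  category <- match.arg(category)
  e <- registry@env
  if (nrow(table) == 0L) return(invisible(0L))
  if (!"key" %in% names(table)) {
    stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(table)),
              !is.null(reference))
    norm <- normalizeVariants(table, reference, registry@build_code)
    table$key <- norm$key
  } else {
    norm <- NULL
  }
  if (is.null(table$detail)) table$detail <- NA_character_
  ## annotation-only records for unseen variants
  if (!is.null(norm)) {
    vid <- variant_id(norm)
    new <- !duplicated(vid) & !(vid %in% e$summary$vid)
    if (any(new)) {
      nv <- norm[new, , drop = FALSE]
      uniq <- vapply(seq_len(nrow(nv)), function(i)
        encodeKey(nv$build_code[i], nv$chrom_code[i], nv$start[i],
                  nv$end[i], nv$alt[i])$unique, logical(1))
      e$summary <- rbind(e$summary, data.frame(
        vid = vid[new], key = nv$key, unique_key = uniq,
        build_code = nv$build_code, chrom = nv$chrom,
        chrom_code = nv$chrom_code, start = nv$start, end = nv$end,
        ref = nv$ref, alt = nv$alt, vtype = nv$vtype,
        effective_size = nv$effective_size, dbsnp = NA_character_,
        stringsAsFactors = FALSE))
    }
    table$vid <- vid
  } else {
    table$vid <- e$summary$vid[match(table$key, e$summary$key)]
    if (anyNA(table$vid))
      stop("key-only annotation rows must reference registered variants")
  }
  add <- data.frame(vid = table$vid, key = table$key, category = category,
                    source = table$source, label = table$label,
                    detail = table$detail, stringsAsFactors = FALSE)
  sig <- do.call(paste, c(add, sep = "\r"))
  have <- do.call(paste, c(e$annot, sep = "\r"))
  add <- add[!sig %in% have & !duplicated(sig), , drop = FALSE]
  e$annot <- rbind(e$annot, add)
  invisible(nrow(add))
}

#' Per-study novelty and pass-rate report
#'
#' For every registered study: the number of distinct variants observed,
#' the number observed in no other study ("unique to study"), and the
#' number whose pass flag is set for that study (at least one contributing
#' record passed the study's quality filters).
#'
#' @param registry A [VariantRegistry].
#' @return data.frame `study`, `variants`, `unique_to_study`, `passed`.
#' @export
noveltyReport <- function(registry) {
  src <- registry@env$sources
  studies <- sort(unique(src$study))
  n_stud <- tapply(src$study, src$vid, function(s) length(unique(s)))
  out <- do.call(rbind, lapply(studies, function(st) {
    rows <- src[src$study == st, , drop = FALSE]
    data.frame(study = st,
               variants = nrow(rows),
               unique_to_study = sum(n_stud[rows$vid] == 1L),
               passed = sum(rows$passed),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(study = character(), variants = integer(),
                      unique_to_study = integer(), passed = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Query registered variants
#'
#' Three equivalent access paths: by exact variant key, by chromosomal
#' location (and optionally alleles), and by a byte-wise key-prefix range
#' scan over a start-position window (see [rangePrefix()]).
#'
#' @param registry A [VariantRegistry].
#' @param key Character vector of key strings.
#' @return Matching rows of the summary table.
#' @export
queryByKey <- function(registry, key) {
  s <- registry@env$summary
  out <- s[s$key %in% key, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname queryByKey
#' @param chrom Contig name.
#' @param start,end Window of start positions (inclusive); `end` defaults
#'   to `start`.
#' @param ref,alt Optional allele filters.
#' @export
queryByLocation <- function(registry, chrom, start, end = start,
                            ref = NULL, alt = NULL) {
  s <- registry@env$summary
  sel <- s$chrom_code == chromCode(chrom) & s$start >= start & s$start <= end
  if (!is.null(ref)) sel <- sel & s$ref == toupper(ref)
  if (!is.null(alt)) sel <- sel & s$alt == toupper(alt)
  out <- s[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname queryByKey
#' @export
queryByRange <- function(registry, chrom, start, end) {
  s <- registry@env$summary
  b <- rangePrefix(registry@build_code, chromCode(chrom), start, end)
  out <- s[keysInRange(s$key, b[1L], b[2L]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write and read a registry as plain-text tables
#'
#' Persists the four backing tables as TSV files in a directory, and loads
#' them back.
#'
#' @param registry A [VariantRegistry].
#' @param dir Directory path (created if needed).
#' @return `writeRegistry()`: invisibly, `dir`.  `readRegistry()`: a
#'   restored [VariantRegistry].
#' @export
writeRegistry <- function(registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in c("summary", "sources", "freqs", "annot"))
    utils::write.table(registry@env[[tab]],
                       file.path(dir, paste0(tab, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(as.character(registry@build_code),
             file.path(dir, "build.txt"))
  invisible(dir)
}

#' @rdname writeRegistry
#' @export
readRegistry <- function(dir) {
  reg <- newRegistry(as.integer(readLines(file.path(dir, "build.txt"))))
  for (tab in c("summary", "sources", "freqs", "annot")) {
    f <- file.path(dir, paste0(tab, ".tsv"))
    tmpl <- reg@env[[tab]]
    got <- utils::read.table(f, sep = "\t", header = TRUE,
                             colClasses = vapply(tmpl, class, character(1)),
                             stringsAsFactors = FALSE)
    reg@env[[tab]] <- got
  }
  reg
}
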