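## Study VCF ingestion (alleles, per-subpopulation AC/AN/AF, FILTER),
## key-annotated VCF output, and TSV/JSON export.
##
## Semantic reading goes through VariantAnnotation::readVcf + expand(),
## which handles multi-allelic decomposition and Number=A INFO fields.
## writeKeyedVcf() edits at the text-line level instead, because its
## contract is byte-compatible preservation of everything but the added
## header line and INFO tag.

#' Default subpopulation INFO field naming
#'
#' Study VCFs are expected to carry allele counts per subpopulation in the
#' `AC_<POP>` / `AN_<POP>` / `AF_<POP>` dialect, plus overall `AC`/`AN`/`AF`
#' reported under the pseudo-subpopulation `"ALL"`.  Studies using another
#' dialect (e.g. `EAS_AF`) supply an explicit map.
#'
#' @param subpops Character vector of subpopulation labels.
#' @return Named list: subpopulation label -> c(AC=, AN=, AF=) INFO keys.
#' @export
subpopFieldMap <- function(subpops) {
  m <- lapply(subpops, function(p)
    c(AC = paste0("AC_", p), AN = paste0("AN_", p), AF = paste0("AF_", p)))
  names(m) <- subpops
  c(list(ALL = c(AC = "AC", AN = "AN", AF = "AF")), m)
}

info_scalar <- function(info, field, i) {
  if (is.null(field) || !field %in% names(info)) return(NA_real_)
  v <- info[[field]][[i]]
  if (length(v) == 0L || is.na(v[1L])) NA_real_ else as.numeric(v[1L])
}

#' Read a study VCF into calls and per-subpopulation frequencies
#'
#' Parses a VCF 4.x file, decomposes multi-allelic records (one output call
#' per ALT allele), and extracts per-subpopulation allele counts (AC),
#' allele numbers (AN) and frequencies (AF) from INFO.  A record passes
#' study filters when FILTER is `PASS` or `.`; when the same variant occurs
#' on several records, passing on any of them suffices (aggregation
#' happens at registration).  Missing AC/AN with a present AF is accepted,
#' with AN left `NA`.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @param study_id Study label attached to every observation.
#' @param field_map Named list mapping subpopulation labels to their
#'   `c(AC=, AN=, AF=)` INFO keys; see [subpopFieldMap()].  Subpopulations
#'   whose INFO keys are absent from the file are dropped with a warning.
#' @return A list with elements
#'   \describe{
#'     \item{calls}{data.frame `rid`, `chrom`, `pos`, `ref`, `alt`,
#'       `filter`, `passed` — one row per ALT allele.}
#'     \item{freqs}{data.frame `rid`, `subpop`, `AC`, `AN`, `AF` (long).}
#'     \item{study_id}{the study label.}
#'   }
#' @export
readStudyVcf <- function(path, study_id, field_map = subpopFieldMap(character())) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  vcf <- VariantAnnotation::expand(vcf)
  n <- length(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (n == 0L) {
    return(list(
      calls = data.frame(rid = integer(), chrom = character(),
                         pos = integer(), ref = character(),
                         alt = character(), filter = character(),
                         passed = logical(), stringsAsFactors = FALSE),
      freqs = data.frame(rid = integer(), subpop = character(),
                         AC = numeric(), AN = numeric(), AF = numeric(),
                         stringsAsFactors = FALSE),
      study_id = study_id))
  }
  filt <- as.character(rr$FILTER)
  calls <- data.frame(
    rid = seq_len(n),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    filter = filt,
    passed = filt %in% c("PASS", "."),
    stringsAsFactors = FALSE
  )
  info <- VariantAnnotation::info(vcf)
  present <- vapply(field_map, function(f)
    any(f %in% names(info)), logical(1))
  if (any(!present))
    warning("INFO fields missing for subpopulation(s): ",
            paste(names(field_map)[!present], collapse = ", "),
            " (observations retained with empty counts)")
  freqs <- do.call(rbind, lapply(names(field_map)[present], function(pop) {
    f <- field_map[[pop]]
    ac <- vapply(seq_len(n), function(i) info_scalar(info, f[["AC"]], i),
                 numeric(1))
    an <- vapply(seq_len(n), function(i) info_scalar(info, f[["AN"]], i),
                 numeric(1))
    af <- vapply(seq_len(n), function(i) info_scalar(info, f[["AF"]], i),
                 numeric(1))
    ## AF derivable from counts takes precedence; AF-only rows keep AN NA
    af <- ifelse(!is.na(ac) & !is.na(an) & an > 0, ac / an, af)
    data.frame(rid = seq_len(n), subpop = pop, AC = ac, AN = an, AF = af,
               stringsAsFactors = FALSE)
  }))
  if (is.null(freqs))
    freqs <- data.frame(rid = integer(), subpop = character(),
                        AC = numeric(), AN = numeric(), AF = numeric(),
                        stringsAsFactors = FALSE)
  freqs <- freqs[!(is.na(freqs$AC) & is.na(freqs$AN) & is.na(freqs$AF)), ,
                 drop = FALSE]
  rownames(freqs) <- NULL
  list(calls = calls, freqs = freqs, study_id = study_id)
}

#' Annotate a VCF with variant keys
#'
#' Adds an `RVSKEY` INFO tag (one key per ALT allele, comma-separated) to
#' every data line of a VCF, writing a new file.  All other content is
#' preserved byte-compatibly; only one header line and the tag are added.
#' Re-running on an already annotated file replaces the existing tag rather
#' than duplicating it.  Records that fail normalization (e.g. symbolic
#' ALTs) are tagged `RVSKEY=.` and logged, not fatal.
#'
#' @param in_path,out_path Input and output VCF paths (plain text).
#' @param reference Reference as from [loadReference()].
#' @param build_code Integer GRCh build (default 37).
#' @return Invisibly, the number of annotated data lines.
#' @export
writeKeyedVcf <- function(in_path, out_path, reference, build_code = 37L) {
  lines <- readLines(in_path)
  is_header <- startsWith(lines, "#")
  hdr <- lines[is_header]
  body <- lines[!is_header]
  tag_line <- paste0('##INFO=<ID=RVSKEY,Number=A,Type=String,',
                     'Description="Reference variant store key">')
  hdr <- hdr[hdr != tag_line]
  ## insert the tag definition just before #CHROM
  chrom_i <- which(startsWith(hdr, "#CHROM"))[1L]
  hdr <- append(hdr, tag_line, after = chrom_i - 1L)
  n_done <- 0L
  body <- vapply(body, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    alts <- strsplit(f[5L], ",", fixed = TRUE)[[1]]
    keys <- vapply(alts, function(a) {
      tryCatch(
        leftAlign(f[1L], as.integer(f[2L]), f[4L], a, reference,
                  build_code)$key,
        error = function(e) {
          message("normalization failed at ", f[1L], ":", f[2L], ": ",
                  conditionMessage(e))
          "."
        })
    }, character(1))
    info <- f[8L]
    info <- gsub("(^|;)RVSKEY=[^;]*", "\\1", info)
    info <- gsub(";;", ";", gsub("^;|;$", "", info))
    tag <- paste0("RVSKEY=", paste(keys, collapse = ","))
    f[8L] <- if (info == "" || info == ".") tag else paste0(info, ";", tag)
    n_done <<- n_done + 1L
    paste(f, collapse = "\t")
  }, character(1), USE.NAMES = FALSE)
  writeLines(c(hdr, body), out_path)
  invisible(n_done)
}

#' Export registry records
#'
#' Writes selected registry records as TSV (one row per variant, frozen
#' column order) or JSON (annotations nested by category: frequencies,
#' impact, phenotype, region).
#'
#' @param registry A [VariantRegistry].
#' @param keys Character vector of variant keys to export; `NULL` exports
#'   the whole store.
#' @param format `"tsv"` or `"json"`.
#' @param path Output file path.
#' @return Invisibly, the number of exported records.
#' @export
exportRecords <- function(registry, path, keys = NULL, format = c("tsv", "json")) {
  format <- match.arg(format)
  s <- registrySummary(registry)
  if (!is.null(keys)) s <- s[s$key %in% keys, , drop = FALSE]
  fr <- registryFrequencies(registry)
  an <- registryAnnotations(registry)
  src <- registrySources(registry)
  if (format == "tsv") {
    fr <- fr[fr$key %in% s$key, , drop = FALSE]
    af_col <- if (nrow(fr)) {
      lab <- paste0(fr$study, ":", fr$subpop, "=", signif(fr$AF, 6))
      tapply(lab, factor(fr$key, levels = s$key),
             function(x) paste(x, collapse = ","))
    } else rep(NA_character_, nrow(s))
    out <- data.frame(
      key = s$key, chrom = s$chrom, start = s$start, end = s$end,
      ref = s$ref, alt = s$alt, type = s$vtype,
      effective_size = s$effective_size, dbsnp = s$dbsnp,
      sources = vapply(s$key, function(k)
        paste(sort(src$study[src$key == k]), collapse = ","), character(1)),
      af = as.character(af_col),
      stringsAsFactors = FALSE
    )
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
  } else {
    recs <- lapply(seq_len(nrow(s)), function(i) {
      k <- s$key[i]
      fi <- fr[fr$key == k, c("study", "subpop", "AC", "AN", "AF"),
               drop = FALSE]
      ai <- an[an$key == k, , drop = FALSE]
      list(
        key = k,
        variant = list(chrom = s$chrom[i], start = s$start[i],
                       end = s$end[i], ref = s$ref[i], alt = s$alt[i],
                       type = s$vtype[i],
                       effective_size = s$effective_size[i],
                       dbsnp = s$dbsnp[i]),
        sources = sort(src$study[src$key == k]),
        frequencies = fi,
        annotations = lapply(split(ai[c("source", "label", "detail")],
                                   ai$category), identity)
      )
    })
    jsonlite::write_json(list(schema = "rvstore-export-1", records = recs),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(nrow(s))
}
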