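## Canonical left-aligned representation of raw variants, plus chromosome
## coding and variant-type classification.

#' Numeric chromosome codes
#'
#' Maps contig names to the store's numeric chromosome representation:
#' 1..22 for the autosomes, X = 23, Y = 24, MT = 25.  Case-insensitive; an
#' optional "chr" prefix is stripped and "M" is accepted for "MT".
#' Unplaced scaffolds are rejected.
#'
#' @param name Character vector of contig names.
#' @return Integer vector of codes in 1..25.
#' @examples
#' chromCode(c("chr1", "X", "MT"))  # 1 23 25
#' @export
chromCode <- function(name) {
  n <- toupper(sub("^chr", "", as.character(name), ignore.case = TRUE))
  n[n == "M"] <- "MT"
  code <- match(n, c(as.character(1:22), "X", "Y", "MT"))
  if (anyNA(code))
    stop("unknown contig: ", paste(unique(name[is.na(code)]), collapse = ", "))
  code
}

#' @rdname chromCode
#' @param code Integer vector of codes in 1..25.
#' @export
chromName <- function(code) {
  code <- as.integer(code)
  if (any(code < 1L | code > 25L)) stop("chromosome code outside 1..25")
  c(as.character(1:22), "X", "Y", "MT")[code]
}

#' Load a reference genome from FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that keeps only the
#' first word of each FASTA header as the contig name.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] usable as the `reference` argument
#'   throughout the package.
#' @export
loadReference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' @rdname loadReference
#' @param reference A `DNAStringSet` (or named character vector of contig
#'   sequences).
#' @param chrom Contig name.
#' @param start,end 1-based inclusive coordinates.
#' @return `refSlice()`: the reference substring as an upper-case character
#'   scalar.
#' @export
refSlice <- function(reference, chrom, start, end) {
  if (end < start) return("")
  if (is.character(reference)) {
    if (!chrom %in% names(reference)) stop("contig not in reference: ", chrom)
    if (end > nchar(reference[[chrom]])) stop("coordinates beyond contig end")
    return(toupper(substr(reference[[chrom]], start, end)))
  }
  i <- match(chrom, names(reference))
  if (is.na(i)) stop("contig not in reference: ", chrom)
  if (end > Biostrings::width(reference)[i]) stop("coordinates beyond contig end")
  toupper(as.character(Biostrings::subseq(reference[[i]], start, end)))
}

#' Classify a trimmed, anchored variant
#'
#' @param ref,alt Reference and alternate allele strings in their canonical
#'   trimmed/anchored form.
#' @return One of `"SNV"`, `"MNV"`, `"INS"`, `"DEL"`, `"INSDEL"`.
#' @examples
#' classifyVariant("A", "T")    # SNV
#' classifyVariant("G", "GA")   # INS
#' @export
classifyVariant <- function(ref, alt) {
  mapply(function(r, a) {
    nr <- nchar(r); na <- nchar(a)
    if (r == a) stop("ref == alt is not a variant")
    if (nr == 1L && na == 1L) return("SNV")
    if (nr == na) return("MNV")
    if (na > nr && startsWith(a, r)) return("INS")
    if (nr > na && startsWith(r, a)) return("DEL")
    "INSDEL"
  }, ref, alt, USE.NAMES = FALSE)
}

#' Effective size of a variant
#'
#' The absolute length difference between reference and alternate allele;
#' 0 for substitutions.  "Small" indels are those of effective size 1000 bp
#' or less.
#'
#' @param ref,alt Allele strings.
#' @return `effectiveSize()`: non-negative integer vector.
#'   `isSmallIndel()`: logical vector, `TRUE` when the effective size is at
#'   most 1000.
#' @export
effectiveSize <- function(ref, alt) {
  abs(nchar(ref) - nchar(alt))
}

#' @rdname effectiveSize
#' @export
isSmallIndel <- function(ref, alt) {
  effectiveSize(ref, alt) <= 1000L
}

#' Left-align and trim a raw variant
#'
#' Produces the unique canonical representation of an edit against the
#' reference: redundant shared prefix/suffix context is trimmed, indels are
#' shifted to their 5'-most equivalent position, and length-changing
#' variants retain a single 5' anchor base (VCF convention) so that REF and
#' ALT are never empty.  Pure substitutions are fully trimmed.  The
#' operation is idempotent and every equivalent spelling of one edit maps
#' to the same output, hence the same variant key.
#'
#' Variants whose left shift reaches position 1 with nothing left to
#' anchor 5' are anchored with the 3' base instead and flagged
#' (`anchor = "3prime"`).
#'
#' @param chrom Contig name.
#' @param pos 1-based position of the first `ref` base.
#' @param ref,alt Allele strings as spelled in the input (case-insensitive;
#'   `ref` must match the reference at `pos`).
#' @param reference Reference as from [loadReference()].
#' @param build_code Integer GRCh build stored with the variant (default 37).
#' @return A one-row data.frame with columns `build_code`, `chrom`,
#'   `chrom_code`, `start`, `end`, `ref`, `alt`, `vtype`, `effective_size`,
#'   `anchor` (`"5prime"`, `"3prime"`, or `"none"` for substitutions) and
#'   `key` (the variant-key text).
#' @examples
#' ref <- c(ctg = "TGCACACACG")
#' leftAlign("ctg", 6, "ACA", "A", ref)  # start 2, ref GCA, alt G, DEL
#' @export
leftAlign <- function(chrom, pos, ref, alt, reference, build_code = 37L) {
  pos <- as.integer(pos)
  ref <- toupper(ref); alt <- toupper(alt)
  if (ref == alt) stop("ref == alt is not a variant")
  clen <- if (is.character(reference)) nchar(reference[[chrom]])
          else Biostrings::width(reference)[match(chrom, names(reference))]
  if (is.na(clen)) stop("contig not in reference: ", chrom)
  if (pos < 1L || pos + nchar(ref) - 1L > clen)
    stop("variant out of contig bounds")
  seen <- refSlice(reference, chrom, pos, pos + nchar(ref) - 1L)
  if (!identical(seen, ref))
    stop("reference mismatch at ", chrom, ":", pos,
         " (expected ", seen, ", got ", ref, ")")

  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  anchor <- "5prime"
  repeat {
    ## trim a shared trailing base; when one allele empties, extend left
    if (length(r) && length(a) && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    } else if (!length(r) || !length(a)) {
      if (pos == 1L) break
      pos <- pos - 1L
      base <- refSlice(reference, chrom, pos, pos)
      r <- c(base, r)
      a <- c(base, a)
    } else break
  }
  ## trim shared leading bases, keeping one anchor for indels
  while (length(r) >= 2L && length(a) >= 2L && r[1L] == a[1L]) {
    r <- r[-1L]
    a <- a[-1L]
    pos <- pos + 1L
  }
  if (length(r) == length(a)) {
    ## pure substitution: drop the anchor if still shared
    if (length(r) >= 2L && r[1L] == a[1L]) {
      r <- r[-1L]; a <- a[-1L]; pos <- pos + 1L
    }
    anchor <- "none"
  } else if (!length(r) || !length(a)) {
    ## indel at contig position 1 with no 5' base: anchor 3'
    base <- refSlice(reference, chrom, pos + max(length(r), 0L),
                     pos + max(length(r), 0L))
    r <- c(r, base)
    a <- c(a, base)
    anchor <- "3prime"
  }
  ref2 <- paste(r, collapse = "")
  alt2 <- paste(a, collapse = "")
  ## contigs outside the 1..22/X/Y/MT coding (ad-hoc test contigs) keep
  ## NA code and key; registration requires codable contigs
  code <- tryCatch(chromCode(chrom), error = function(e) NA_integer_)
  data.frame(
    build_code = as.integer(build_code),
    chrom = chrom,
    chrom_code = code,
    start = pos,
    end = pos + nchar(ref2) - 1L,
    ref = ref2,
    alt = alt2,
    vtype = classifyVariant(ref2, alt2),
    effective_size = effectiveSize(ref2, alt2),
    anchor = anchor,
    key = if (is.na(code)) NA_character_ else
      encodeKey(build_code, code, pos, pos + nchar(ref2) - 1L, alt2)$text,
    stringsAsFactors = FALSE
  )
}

#' Normalize a table of raw variants
#'
#' Vectorized driver over [leftAlign()]: one row in, one canonical row out,
#' preserving the input order and any extra columns.
#'
#' @param raw A data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @inheritParams leftAlign
#' @return A data.frame of canonical variants (columns as in
#'   [leftAlign()]), with the extra input columns carried through.
#' @export
normalizeVariants <- function(raw, reference, build_code = 37L) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(raw)))
  if (nrow(raw) == 0L) {
    out <- leftAlign("X", 1, "A", "T", c(X = "AC"))[0L, ]
    return(out)
  }
  norm <- do.call(rbind, lapply(seq_len(nrow(raw)), function(i) {
    leftAlign(raw$chrom[i], raw$pos[i], raw$ref[i], raw$alt[i],
              reference, build_code)
  }))
  extra <- setdiff(names(raw), c(names(norm), "pos"))
  for (cn in extra) norm[[cn]] <- raw[[cn]]
  rownames(norm) <- NULL
  norm
}
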