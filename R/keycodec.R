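## Variant-key codec: a reversible, byte-sortable base-64 identifier for
## small variants.  Layout (fixed-width header, variable tail):
##   char 1      genome build (GRCh version encoded as alphabet index)
##   char 2      chromosome code (1..22, X=23, Y=24, MT=25)
##   chars 3-7   start position (1-based, big-endian base 64)
##   chars 8-12  end position   (= start + nchar(ref) - 1)
##   chars 13-14 alternate-allele length (0..4095)
##   chars 15-   packed alternate allele, 3 nucleotides per character
## Total key length is capped at KEY_MAX_CHARS characters; alleles that do
## not fit are truncated and the key flagged non-unique.

## 64 symbols in strictly increasing byte order: digits, '@', upper case,
## '_', lower case.  Byte-wise string sort therefore equals index sort.
KEY_ALPHABET <- c(
  strsplit("0123456789", "")[[1]],
  "@", LETTERS, "_", letters
)

## inverse lookup: ASCII byte -> 0-based alphabet index (NA if not a symbol)
KEY_INDEX <- local({
  idx <- rep(NA_integer_, 127L)
  idx[utf8ToInt(paste(KEY_ALPHABET, collapse = ""))] <- seq_along(KEY_ALPHABET) - 1L
  idx
})

KEY_MAX_CHARS <- 1000L
KEY_HEADER_CHARS <- 14L
NUC <- c("A", "C", "G", "T")

#' Key-format capacity constants
#'
#' The variant key stores the alternate-allele length in a fixed-width
#' two-symbol base-64 field, so the longest representable allele is
#' \eqn{64^2 - 1 = 4095} nucleotides.  The total key is capped at 1000
#' characters; after the 14-character header that leaves room for
#' \eqn{(1000 - 14) \times 3 = 2958} packed nucleotides, the longest
#' alternate allele whose key is still unique (losslessly reversible).
#'
#' Both values are computed from the format, not hard-coded.
#'
#' @return `keyAltLenMax()`: the capacity of the allele-length field, in
#'   nucleotides.  `keyUniqueAltMax()`: the longest alternate allele with a
#'   unique key, in nucleotides.
#' @examples
#' keyAltLenMax()     # 4095
#' keyUniqueAltMax()  # 2958
#' @export
keyAltLenMax <- function() {
  as.integer(length(KEY_ALPHABET)^2 - 1)
}

#' @rdname keyAltLenMax
#' @export
keyUniqueAltMax <- function() {
  (KEY_MAX_CHARS - KEY_HEADER_CHARS) * 3L
}

#' Fixed-width base-64 integer encoding
#'
#' Encodes a non-negative integer as exactly `width` symbols of the key
#' alphabet, big-endian, so that numeric order of values equals byte order
#' of the encoded strings at a given width.
#'
#' @param value Non-negative integer vector (doubles accepted for values
#'   beyond `.Machine$integer.max`).
#' @param width Number of output symbols; `value` must be `< 64^width`.
#' @return Character vector of `width`-character strings.
#' @examples
#' encodeInt(0, 5)   # "00000"
#' encodeInt(64, 2)  # "10"
#' decodeInt("0@")   # 10
#' @export
encodeInt <- function(value, width) {
  width <- as.integer(width)
  stopifnot(length(width) == 1L, width >= 1L)
  value <- as.numeric(value)
  if (any(is.na(value)) || any(value < 0))
    stop("'value' must be non-negative")
  if (any(value >= 64^width))
    stop("value overflows a ", width, "-symbol base-64 field")
  out <- matrix("", nrow = width, ncol = length(value))
  v <- floor(value)
  for (i in width:1) {
    out[i, ] <- KEY_ALPHABET[(v %% 64) + 1L]
    v <- v %/% 64
  }
  apply(out, 2L, paste, collapse = "")
}

#' @rdname encodeInt
#' @param text Character vector of base-64 strings over the key alphabet.
#' @export
decodeInt <- function(text) {
  vapply(text, function(s) {
    b <- utf8ToInt(s)
    if (any(b < 1L | b > 127L)) stop("character outside key alphabet")
    d <- KEY_INDEX[b]
    if (anyNA(d)) stop("character outside key alphabet in '", s, "'")
    sum(d * 64^(rev(seq_along(d)) - 1))
  }, numeric(1), USE.NAMES = FALSE)
}

## nucleotide -> 2-bit value lookup (A=0, C=1, G=2, T=3), by ASCII byte
NUC_VAL <- local({
  v <- rep(NA_integer_, 127L)
  v[utf8ToInt("ACGT")] <- 0:3
  v
})

#' Pack and unpack alternate alleles
#'
#' Alternate alleles over \{A, C, G, T\} are compressed at three
#' nucleotides per key symbol (each base is 2 bits; \eqn{4^3 = 64}).  The
#' final triplet is zero-padded; the separately stored allele length
#' disambiguates the padding, so packing is lossless.
#'
#' Alleles containing any other character (N, IUPAC codes, symbolic ALTs)
#' are rejected; [encodeKey()] routes such variants to a non-unique key
#' with an empty packed allele.
#'
#' @param seq Nucleotide string over ACGT (empty allowed).
#' @return `packAllele()`: a base-64 string of `ceiling(nchar(seq)/3)`
#'   symbols.  `unpackAllele()`: the original nucleotide string.
#' @examples
#' packAllele("AAA")      # "0"
#' packAllele("T")        # "k"
#' unpackAllele("k", 1)   # "T"
#' @export
packAllele <- function(seq) {
  stopifnot(length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  b <- utf8ToInt(seq)
  if (any(b < 1L | b > 127L)) stop("allele contains non-ACGT character")
  v <- NUC_VAL[b]
  if (anyNA(v)) stop("allele contains non-ACGT character")
  pad <- (3L - length(v) %% 3L) %% 3L
  v <- c(v, integer(pad))
  m <- matrix(v, nrow = 3L)
  vals <- 16L * m[1L, ] + 4L * m[2L, ] + m[3L, ]
  paste(KEY_ALPHABET[vals + 1L], collapse = "")
}

#' @rdname packAllele
#' @param packed Packed base-64 string as produced by `packAllele()`.
#' @param alt_len Length of the original allele in nucleotides; must satisfy
#'   `nchar(packed) == ceiling(alt_len/3)`.
#' @export
unpackAllele <- function(packed, alt_len) {
  stopifnot(length(packed) == 1L, length(alt_len) == 1L)
  alt_len <- as.integer(alt_len)
  if (nchar(packed) != ceiling(alt_len / 3))
    stop("packed length ", nchar(packed),
         " does not match allele length ", alt_len)
  if (alt_len == 0L) return("")
  d <- KEY_INDEX[utf8ToInt(packed)]
  if (anyNA(d)) stop("character outside key alphabet")
  tri <- rbind(d %/% 16L, (d %/% 4L) %% 4L, d %% 4L)
  paste(NUC[tri[seq_len(alt_len)] + 1L], collapse = "")
}

#' Encode a normalized variant as its variant key
#'
#' Builds the reversible, byte-sortable key from a left-aligned variant's
#' build, chromosome code, start, end, and alternate allele.  The key is
#' unique (losslessly reversible) for SNVs, deletions, and insertions/MNVs
#' with up to [keyUniqueAltMax()] alternate nucleotides; longer or
#' non-ACGT alleles get a truncated/empty packed allele and
#' `unique = FALSE`, and such variants should be retrieved by location and
#' alternate allele instead.
#'
#' @param build_code Integer GRCh version (36, 37, or 38 typically); must
#'   be a valid single-symbol alphabet index (0..63).
#' @param chrom_code Integer chromosome code 1..25 (see [chromCode()]).
#' @param start,end 1-based inclusive coordinates; `end = start +
#'   nchar(ref) - 1`.
#' @param alt Alternate allele string (upper case).
#' @return A list of class `"VariantKey"` with elements `text`,
#'   `build_code`, `chrom_code`, `start`, `end`, `alt_len`, `unique`.
#' @examples
#' k <- encodeKey(37, 1, 100, 100, "T")
#' nchar(k$text)  # 15
#' decodeKey(k$text)$alt  # "T"
#' @export
encodeKey <- function(build_code, chrom_code, start, end, alt) {
  build_code <- as.integer(build_code)
  chrom_code <- as.integer(chrom_code)
  if (build_code < 0L || build_code > 63L)
    stop("build code must be representable in one key symbol (0..63)")
  if (chrom_code < 1L || chrom_code > 25L)
    stop("chromosome code must be in 1..25")
  if (start < 1L || start >= 64^5 || end < 0L || end >= 64^5)
    stop("position out of range for a 5-symbol field")
  alt_len <- nchar(alt)
  if (alt_len > keyAltLenMax())
    stop("alternate allele longer than ", keyAltLenMax(),
         " nt cannot be stored in the length field")
  packed <- tryCatch(packAllele(alt), error = function(e) NULL)
  uniq <- !is.null(packed) && alt_len <= keyUniqueAltMax()
  if (is.null(packed)) {
    packed <- ""                      # non-ACGT: empty packed allele
  } else if (alt_len > keyUniqueAltMax()) {
    packed <- substr(packed, 1L, KEY_MAX_CHARS - KEY_HEADER_CHARS)
  }
  text <- paste0(
    KEY_ALPHABET[build_code + 1L],
    KEY_ALPHABET[chrom_code + 1L],
    encodeInt(start, 5L),
    encodeInt(end, 5L),
    encodeInt(alt_len, 2L),
    packed
  )
  structure(
    list(text = text, build_code = build_code, chrom_code = chrom_code,
         start = start, end = end, alt_len = alt_len, unique = uniq),
    class = "VariantKey"
  )
}

#' @export
print.VariantKey <- function(x, ...) {
  cat("VariantKey ", x$text, "\n  build GRCh", x$build_code,
      ", chrom code ", x$chrom_code, ", ", x$start, "-", x$end,
      ", alt length ", x$alt_len,
      if (!x$unique) " [non-unique]", "\n", sep = "")
  invisible(x)
}

#' Decode a variant key back to its fields
#'
#' Recovers build, chromosome code, start, end, and the alternate allele
#' from the key text.  The reference allele is not stored in the key; when
#' a reference accessor is supplied it is filled from the span
#' `start..end`, otherwise left `NA`.
#'
#' @param text Key string.
#' @param reference Optional reference, as returned by [loadReference()],
#'   used to fill the `ref` field.
#' @return A list with `build_code`, `chrom_code`, `chrom`, `start`, `end`,
#'   `alt_len`, `alt`, `ref`, `unique`.  When the packed allele was
#'   truncated (`unique = FALSE`) `alt` holds the truncated prefix and a
#'   warning is raised.
#' @export
decodeKey <- function(text, reference = NULL) {
  stopifnot(length(text) == 1L)
  if (nchar(text) < KEY_HEADER_CHARS)
    stop("malformed key: shorter than the 14-character header")
  d <- KEY_INDEX[utf8ToInt(text)]
  if (anyNA(d)) stop("malformed key: illegal character")
  build <- d[1L]
  chrom <- d[2L]
  if (chrom < 1L || chrom > 25L)
    stop("malformed key: chromosome code ", chrom, " outside 1..25")
  start <- as.integer(decodeInt(substr(text, 3L, 7L)))   # 64^5 < 2^31
  end <- as.integer(decodeInt(substr(text, 8L, 12L)))
  alt_len <- as.integer(decodeInt(substr(text, 13L, 14L)))
  packed <- substr(text, 15L, nchar(text))
  expect_chars <- ceiling(alt_len / 3)
  uniq <- TRUE
  if (nchar(packed) == expect_chars) {
    alt <- unpackAllele(packed, alt_len)
  } else if (nchar(packed) < expect_chars) {
    ## truncated (long insertion) or absent (non-ACGT) packed allele
    uniq <- FALSE
    warning("non-unique key: packed allele truncated or absent; ",
            "retrieve by location and alternate allele")
    alt <- if (nchar(packed) > 0L)
      unpackAllele(packed, 3L * nchar(packed)) else NA_character_
  } else {
    stop("malformed key: packed allele longer than the length field allows")
  }
  chrom_name <- chromName(chrom)
  ref <- NA_character_
  if (!is.null(reference) && end >= start)
    ref <- refSlice(reference, chrom_name, start, end)
  list(build_code = build, chrom_code = chrom, chrom = chrom_name,
       start = start, end = end, alt_len = alt_len, alt = alt, ref = ref,
       unique = uniq)
}

#' Key-prefix bounds for a genomic window
#'
#' Because keys sort byte-wise in genomic order, all keys on a chromosome
#' with start position inside `[start_lo, start_hi]` fall byte-wise between
#' the two returned bounds (inclusive).  Useful for range scans over a
#' key-sorted store.
#'
#' @inheritParams encodeKey
#' @param start_lo,start_hi Window of start positions, inclusive.
#' @return Character vector `c(lo, hi)`.
#' @export
rangePrefix <- function(build_code, chrom_code, start_lo, start_hi) {
  if (start_lo > start_hi) stop("inverted window: start_lo > start_hi")
  prefix <- function(s) paste0(
    KEY_ALPHABET[as.integer(build_code) + 1L],
    KEY_ALPHABET[as.integer(chrom_code) + 1L],
    encodeInt(s, 5L)
  )
  ## pad the upper bound past any possible key tail with the top symbol
  hi <- paste0(prefix(start_hi),
               strrep(KEY_ALPHABET[64L], KEY_MAX_CHARS - 7L))
  c(prefix(start_lo), hi)
}

#' Byte-wise key comparison helpers
#'
#' R's string collation is locale-dependent; key order is defined byte-wise.
#' `keyOrder()` returns the permutation sorting keys in byte order and
#' `keysInRange()` tests membership between two byte-wise bounds
#' (inclusive), as produced by [rangePrefix()].
#'
#' @param keys Character vector of key strings.
#' @return `keyOrder()`: integer permutation. `keysInRange()`: logical
#'   vector.
#' @export
keyOrder <- function(keys) {
  order(keys, method = "radix")
}

#' @rdname keyOrder
#' @param lo,hi Inclusive byte-wise bounds.
#' @export
keysInRange <- function(keys, lo, hi) {
  cmp <- function(a, b) {       # -1, 0, 1 byte-wise
    x <- utf8ToInt(a); y <- utf8ToInt(b)
    n <- min(length(x), length(y))
    i <- which(x[seq_len(n)] != y[seq_len(n)])
    if (length(i)) return(sign(x[i[1L]] - y[i[1L]]))
    sign(length(x) - length(y))
  }
  vapply(keys, function(k) cmp(k, lo) >= 0 && cmp(k, hi) <= 0,
         logical(1), USE.NAMES = FALSE)
}
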