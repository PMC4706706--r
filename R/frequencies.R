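## Allele-frequency aggregation across studies and subpopulations,
## max-ethnicity AF, and the clinical frequency-bin table.

## bin lower edges; intervals are half-open [lower, upper) except the last,
## and AF == 0 (unobserved) is its own bin
AF_BIN_EDGES <- c(0, 0.001, 0.005, 0.01, 0.05, 0.1, 0.5)

#' Allele-frequency bin labels
#'
#' The eight non-cumulative bins used for clinical-variant frequency
#' tables: a dedicated bin for AF exactly 0 (never observed), then
#' half-open intervals whose upper boundary is excluded, and a final
#' unbounded bin from 0.5 up.
#'
#' @return Character vector of the eight bin labels in order.
#' @export
afBinLabels <- function() {
  c("0", "0-0.001", "0.001-0.005", "0.005-0.01", "0.01-0.05",
    "0.05-0.1", "0.1-0.5", ">=0.5")
}

#' Assign allele frequencies to bins
#'
#' @param af Numeric vector of allele frequencies in `[0, 1]`.
#' @return Factor with levels [afBinLabels()].  `binAF(0)` is `"0"`;
#'   boundaries belong to the upper bin (e.g. 0.001 falls in
#'   `"0.001-0.005"`, 0.5 in `">=0.5"`).
#' @examples
#' binAF(c(0, 0.0005, 0.001, 0.5))
#' @export
binAF <- function(af) {
  if (any(is.na(af)) || any(af < 0 | af > 1))
    stop("allele frequencies must be in [0, 1]")
  lab <- afBinLabels()
  idx <- findInterval(af, AF_BIN_EDGES) + 1L  # af>0 -> 2..8
  idx[af == 0] <- 1L
  factor(lab[idx], levels = lab)
}

#' Maximum ethnicity-specific allele frequency
#'
#' For each variant, the highest allele frequency found for any
#' (study, subpopulation) pair within the given cohort set.  Studies
#' without a subpopulation breakdown contribute their overall AF (stored
#' under the `"ALL"` pseudo-subpopulation).  Variants absent from every
#' cohort get 0.
#'
#' @param registry A [VariantRegistry].
#' @param keys Character vector of variant keys.
#' @param studies Character vector of study labels to consider; `NULL`
#'   means every study in the store.
#' @return Named numeric vector of maxima, in the order of `keys`.
#' @export
maxEthnicityAF <- function(registry, keys, studies = NULL) {
  fr <- registry@env$freqs
  if (is.null(studies)) studies <- unique(fr$study)
  known <- unique(c(registry@env$sources$study, fr$study))
  bad <- setdiff(studies, known)
  if (length(bad))
    stop("unknown study: ", paste(bad, collapse = ", "))
  fr <- fr[fr$study %in% studies & !is.na(fr$AF), , drop = FALSE]
  mx <- tapply(fr$AF, factor(fr$key, levels = unique(keys)), max)
  out <- as.numeric(mx[match(keys, unique(keys))])
  out[is.na(out)] <- 0
  names(out) <- keys
  out
}

sig_severity <- c("pathogenic", "likely_pathogenic", "risk_factor",
                  "association", "drug_response", "protective",
                  "likely_benign", "benign", "VUS", "other", "unknown")

#' Clinical significance vocabulary
#'
#' The closed set of significance labels accepted in clinical assertion
#' tables, ordered from most to least severe (the order used to pick a
#' representative label when one source asserts several non-contradictory
#' labels for a variant).
#'
#' @return Character vector of labels.
#' @export
significanceLevels <- function() sig_severity

#' Bin clinically asserted variants by maximum ethnicity AF
#'
#' Builds the percentage table of clinically asserted variants per
#' (source, significance) group across allele-frequency bins.  For each
#' variant the maximum ethnicity-specific AF over the given cohort set is
#' used.  Within each source, variants asserted with contradicting
#' pathogenicities (at least one of pathogenic/likely_pathogenic and at
#' least one of benign/likely_benign, from that source) are excluded
#' before binning; other label mixtures are kept under their most severe
#' label.  Cell values are percentages of the source's total retained
#' variants, so each source's cells sum to 100.
#'
#' @param registry A [VariantRegistry] whose `phenotype` annotations carry
#'   the assertions (`source`, `label` = significance).
#' @param studies Cohort set for [maxEthnicityAF()]; `NULL` = all studies.
#' @return A list with `percent` (matrix, rows "source: significance",
#'   columns [afBinLabels()] plus `Total`), `counts` (same shape, raw
#'   counts), and `excluded` (data.frame of contradictory key/source
#'   pairs).
#' @export
clinicalBinTable <- function(registry, studies = NULL) {
  an <- registry@env$annot
  an <- an[an$category == "phenotype", , drop = FALSE]
  if (nrow(an) == 0L) {
    warning("no clinical assertions in the registry")
    m <- matrix(numeric(0), 0, length(afBinLabels()) + 1L,
                dimnames = list(NULL, c(afBinLabels(), "Total")))
    return(list(percent = m, counts = m,
                excluded = data.frame(key = character(),
                                      source = character())))
  }
  bad <- !an$label %in% sig_severity
  if (any(bad))
    stop("significance label outside the closed vocabulary: ",
         paste(unique(an$label[bad]), collapse = ", "))
  ## contradiction rule, per source
  grp <- paste(an$source, an$key, sep = "\r")
  has_path <- tapply(an$label %in% c("pathogenic", "likely_pathogenic"),
                     grp, any)
  has_ben <- tapply(an$label %in% c("benign", "likely_benign"), grp, any)
  contra <- names(has_path)[has_path & has_ben]
  excluded <- unique(an[grp %in% contra, c("key", "source")])
  rownames(excluded) <- NULL
  an <- an[!grp %in% contra, , drop = FALSE]
  ## one row per (source, key): most severe label
  sev <- match(an$label, sig_severity)
  o <- order(an$source, an$key, sev)
  an <- an[o, , drop = FALSE]
  an <- an[!duplicated(an[c("source", "key")]), , drop = FALSE]
  af <- maxEthnicityAF(registry, an$key, studies)
  bin <- binAF(af)
  row_lab <- paste0(an$source, ": ", an$label)
  levels_row <- unique(row_lab[order(an$source, match(an$label,
                                                      sig_severity))])
  counts <- table(factor(row_lab, levels = levels_row), bin)
  counts <- cbind(as.matrix(unclass(counts)), Total = rowSums(counts))
  src_of_row <- sub(":.*$", "", rownames(counts))
  src_tot <- tapply(counts[, "Total"], src_of_row, sum)[src_of_row]
  pct <- 100 * counts / as.numeric(src_tot)
  list(percent = pct, counts = counts, excluded = excluded)
}

#' @rdname clinicalBinTable
#' @param x Result of `clinicalBinTable()`.
#' @param digits Decimals for the printed percentages.
#' @export
formatBinTable <- function(x, digits = 2) {
  m <- round(x$percent, digits)
  noquote(ifelse(x$counts > 0 | col(m) > ncol(m) - 1L,
                 formatC(m, format = "f", digits = digits), ""))
}
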