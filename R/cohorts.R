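## Cross-cohort analyses: exact-test AF-difference screening,
## pathogenic-but-common flagging, and disease-exclusive discovery.

#' Define a cohort over registered studies
#'
#' A cohort is a named set of (study, subpopulation) members with a role.
#' A member with subpopulation `NA` contributes the study's overall
#' counts (the `"ALL"` pseudo-subpopulation).
#'
#' @param name Cohort name.
#' @param members data.frame with columns `study` and optionally `subpop`
#'   (default `NA` = overall), or a character vector of study labels.
#' @param role `"healthy"` or `"disease"`.
#' @return A `CohortSpec` object.
#' @export
cohortSpec <- function(name, members, role = c("healthy", "disease")) {
  role <- match.arg(role)
  if (is.character(members))
    members <- data.frame(study = members, subpop = NA_character_,
                          stringsAsFactors = FALSE)
  if (is.null(members$subpop)) members$subpop <- NA_character_
  stopifnot(nrow(members) > 0L)
  methods::new("CohortSpec", name = name, members = members, role = role)
}

setClass("CohortSpec",
  representation(name = "character", members = "data.frame",
                 role = "character"))

setValidity("CohortSpec", function(object) {
  if (nrow(object@members) == 0L) return("cohort must have members")
  if (!object@role %in% c("healthy", "disease"))
    return("role must be 'healthy' or 'disease'")
  TRUE
})

#' @export
setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec '", object@name, "' (", object@role, "): ",
      paste(ifelse(is.na(object@members$subpop), object@members$study,
                   paste0(object@members$study, "/",
                          object@members$subpop)), collapse = ", "),
      "\n", sep = "")
})

## Aggregate AC/AN per variant over the cohort's members.  has_counts is
## FALSE when any contributing row carries AF without AN.
cohort_counts <- function(registry, cohort) {
  fr <- registry@env$freqs
  m <- cohort@members
  known <- unique(fr$study)
  bad <- setdiff(m$study, unique(c(known, registry@env$sources$study)))
  if (length(bad))
    stop("unknown study in cohort '", cohort@name, "': ",
         paste(bad, collapse = ", "))
  pick <- rep(FALSE, nrow(fr))
  for (i in seq_len(nrow(m))) {
    sp <- if (is.na(m$subpop[i])) "ALL" else m$subpop[i]
    pick <- pick | (fr$study == m$study[i] & fr$subpop == sp)
  }
  fr <- fr[pick, , drop = FALSE]
  if (nrow(fr) == 0L)
    return(data.frame(key = character(), AC = numeric(), AN = numeric(),
                      AF = numeric(), has_counts = logical(),
                      stringsAsFactors = FALSE))
  k <- factor(fr$key, levels = unique(fr$key))
  has <- as.logical(tapply(!is.na(fr$AC) & !is.na(fr$AN), k, all))
  ac <- as.numeric(tapply(ifelse(is.na(fr$AC), 0, fr$AC), k, sum))
  an <- as.numeric(tapply(ifelse(is.na(fr$AN), 0, fr$AN), k, sum))
  af <- as.numeric(tapply(fr$AF, k, max))      # fallback when counts absent
  data.frame(key = levels(k), AC = ac, AN = an,
             AF = ifelse(an > 0, ac / an, af), has_counts = has,
             stringsAsFactors = FALSE)
}

#' Vectorized two-sided exact test on 2x2 allele-count tables
#'
#' Computes, for each variant, the two-sided Fisher exact p-value of the
#' table `[(AC_a, AN_a - AC_a), (AC_b, AN_b - AC_b)]` by summing the
#' conditional hypergeometric probabilities of all tables (with the same
#' margins) no more probable than the observed one, using the standard
#' relative tie tolerance of 1e-7.  Equivalent to
#' `stats::fisher.test()$p.value` on each table, but vectorized so that
#' large screens and exhaustive table sweeps are feasible.
#'
#' @param ac_a,an_a,ac_b,an_b Integer vectors: alternate-allele counts and
#'   total allele numbers in the two cohorts.
#' @return Numeric vector of p-values.
#' @export
exactTest2x2 <- function(ac_a, an_a, ac_b, an_b) {
  stopifnot(all(ac_a >= 0), all(ac_b >= 0),
            all(ac_a <= an_a), all(ac_b <= an_b))
  n <- max(length(ac_a), length(an_a), length(ac_b), length(an_b))
  ac_a <- rep_len(ac_a, n); an_a <- rep_len(an_a, n)
  ac_b <- rep_len(ac_b, n); an_b <- rep_len(an_b, n)
  p <- numeric(n)
  for (i in seq_len(n)) {
    K <- ac_a[i] + ac_b[i]                 # total ALT alleles
    N <- an_a[i] + an_b[i]
    lo <- max(0L, K - an_b[i])
    hi <- min(K, an_a[i])
    d <- stats::dhyper(lo:hi, K, N - K, an_a[i])
    keep <- d <= d[ac_a[i] - lo + 1L] * (1 + 1e-7)
    ## every table included (observed is modal): exactly 1, not 1 - eps
    p[i] <- if (all(keep)) 1 else min(1, sum(d[keep]))
  }
  p
}

#' Screen two cohorts for allele-frequency differences
#'
#' Per variant present in either cohort, runs a two-sided Fisher exact
#' test on the aggregated 2x2 allele-count table, adjusts for multiplicity
#' with Benjamini-Hochberg, and returns the variants significant at the
#' requested FDR, sorted by q-value.  When a cohort carries AF without
#' allele numbers for some variant the test is impossible there; those
#' variants are returned with `p`/`q` `NA` and `tested = FALSE`, reporting
#' the AF difference only.
#'
#' @param registry A [VariantRegistry].
#' @param a,b [cohortSpec()] objects.
#' @param alpha FDR threshold on q-values (default 0.05).
#' @param filters Optional character vector of impact labels; only
#'   variants carrying a matching `impact` annotation are screened.
#' @param all_results Return every tested variant instead of only the
#'   significant ones (used by oracles and calibration).
#' @return data.frame `key`, `af_a`, `af_b`, `ac_a`, `an_a`, `ac_b`,
#'   `an_b`, `p`, `q`, `tested`.
#' @export
compareCohorts <- function(registry, a, b, alpha = 0.05, filters = NULL,
                           all_results = FALSE) {
  ca <- cohort_counts(registry, a)
  cb <- cohort_counts(registry, b)
  keys <- union(ca$key, cb$key)
  if (!is.null(filters)) {
    an <- registry@env$annot
    keep <- an$key[an$category == "impact" & an$label %in% filters]
    keys <- intersect(keys, keep)
  }
  ia <- match(keys, ca$key)
  ib <- match(keys, cb$key)
  ac_a <- ifelse(is.na(ia), 0, ca$AC[ia])
  an_a <- ifelse(is.na(ia), NA, ca$AN[ia])
  ac_b <- ifelse(is.na(ib), 0, cb$AC[ib])
  an_b <- ifelse(is.na(ib), NA, cb$AN[ib])
  ## absent from one cohort: zero carriers out of that cohort's AN; take
  ## the cohort-wide maximum AN as the denominator for absentees
  an_a[is.na(an_a)] <- if (nrow(ca)) max(ca$AN) else NA
  an_b[is.na(an_b)] <- if (nrow(cb)) max(cb$AN) else NA
  has_a <- ifelse(is.na(ia), nrow(ca) > 0 && all(ca$has_counts),
                  ca$has_counts[ia])
  has_b <- ifelse(is.na(ib), nrow(cb) > 0 && all(cb$has_counts),
                  cb$has_counts[ib])
  tested <- has_a & has_b & !is.na(an_a) & !is.na(an_b) &
    an_a > 0 & an_b > 0
  if (!all(tested))
    warning(sum(!tested), " variant(s) lack allele counts in a cohort; ",
            "reporting AF delta only for those")
  p <- rep(NA_real_, length(keys))
  p[tested] <- exactTest2x2(ac_a[tested], an_a[tested],
                            ac_b[tested], an_b[tested])
  q <- rep(NA_real_, length(keys))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  out <- data.frame(
    key = keys,
    af_a = ifelse(tested | !is.na(ia) & an_a > 0, ac_a / an_a,
                  ifelse(is.na(ia), 0, ca$AF[ia])),
    af_b = ifelse(tested | !is.na(ib) & an_b > 0, ac_b / an_b,
                  ifelse(is.na(ib), 0, cb$AF[ib])),
    ac_a = ac_a, an_a = an_a, ac_b = ac_b, an_b = an_b,
    p = p, q = q, tested = tested, stringsAsFactors = FALSE)
  if (!all_results)
    out <- out[(!out$tested) | (!is.na(out$q) & out$q < alpha), ,
               drop = FALSE]
  out <- out[order(out$q, out$p, out$key, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag clinically asserted variants that are common in healthy cohorts
#'
#' Under the assumption that a truly pathogenic variant should not be
#' common in any healthy population, returns every clinically asserted
#' variant whose maximum ethnicity-specific allele frequency across the
#' given healthy cohorts reaches the threshold, grouped by significance.
#' The default threshold is 1% allele frequency in any population; 0.1%
#' is the stricter alternative appropriate for autosomal dominant
#' disorders.
#'
#' @param registry A [VariantRegistry] with `phenotype` annotations.
#' @param studies Healthy study labels whose frequencies are scanned;
#'   `NULL` = all studies.
#' @param threshold AF threshold (default 0.01).
#' @return data.frame `key`, `source`, `significance`, `max_af`, sorted by
#'   decreasing `max_af`, one row per (variant, source, significance).
#' @export
flagPathogenicCommon <- function(registry, studies = NULL, threshold = 0.01) {
  an <- registry@env$annot
  an <- an[an$category == "phenotype", , drop = FALSE]
  an <- unique(an[c("key", "source", "label")])
  if (nrow(an) == 0L)
    return(data.frame(key = character(), source = character(),
                      significance = character(), max_af = numeric(),
                      stringsAsFactors = FALSE))
  af <- maxEthnicityAF(registry, an$key, studies)
  sel <- af >= threshold
  out <- data.frame(key = an$key[sel], source = an$source[sel],
                    significance = an$label[sel],
                    max_af = as.numeric(af[sel]), stringsAsFactors = FALSE)
  out <- out[order(-out$max_af, out$key, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variants observed exclusively in a disease cohort
#'
#' Returns the variants carried in the disease cohort (aggregate AC > 0)
#' with no carriers (AC == 0 or never observed) in every background
#' cohort.  Optional impact filters and a pass-flag filter narrow the
#' candidates.  Adding a background cohort can only shrink the result.
#'
#' @param registry A [VariantRegistry].
#' @param disease A [cohortSpec()] with role `"disease"`.
#' @param backgrounds List of background [cohortSpec()]s (healthy or other
#'   disease populations to exclude against).
#' @param filters Optional impact labels (as in [compareCohorts()]).
#' @param passed_only Keep only variants whose pass flag is set in at
#'   least one disease-cohort study.
#' @return Character vector of variant keys, byte-sorted.
#' @export
exclusiveToCohort <- function(registry, disease, backgrounds,
                              filters = NULL, passed_only = FALSE) {
  cd <- cohort_counts(registry, disease)
  keys <- cd$key[cd$AC > 0]
  for (bg in backgrounds) {
    cb <- cohort_counts(registry, bg)
    keys <- setdiff(keys, cb$key[cb$AC > 0])
  }
  if (!is.null(filters)) {
    an <- registry@env$annot
    keys <- intersect(keys,
                      an$key[an$category == "impact" & an$label %in% filters])
  }
  if (passed_only) {
    src <- registrySources(registry)
    ok <- src$key[src$study %in% disease@members$study & src$passed]
    keys <- intersect(keys, ok)
  }
  sort(keys, method = "radix")
}
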