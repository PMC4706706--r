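## Deterministic simulator for the whole pipeline: reference contigs with
## repeat tracts, multi-study cohort VCFs with subpopulation AC/AN/AF and
## planted FILTER failures, clinical assertion tables with planted
## contradictions, and denormalized (non-left-aligned) variant spellings.
##
## All randomness is consumed inside simDesign(): the design object holds
## the fully realized truth (contig sequences, per-study observations,
## assertions), and the make*() writers are deterministic renderings of
## it, so regenerating any file is bit-reproducible.

setClass("SimDesign",
  representation(seed = "integer", contigs = "character",
                 studies = "data.frame", subpops = "list",
                 variants = "data.frame", freqs = "data.frame",
                 assertions = "data.frame", params = "list"))

#' @export
setMethod("show", "SimDesign", function(object) {
  cat("SimDesign (seed ", object@seed, ")\n", sep = "")
  cat("  contigs:  ", paste0(names(object@contigs), " (",
      nchar(object@contigs), " bp)", collapse = ", "), "\n", sep = "")
  cat("  studies:  ", paste0(object@studies$study, " (",
      object@studies$n_samples, " samples, ", object@studies$role, ")",
      collapse = ", "), "\n", sep = "")
  cat("  variants: ", nrow(object@variants), " sites; ",
      nrow(object@assertions), " clinical assertions\n", sep = "")
})

#' Enumerate all equivalent raw spellings of an edit
#'
#' Brute force over a reference window: every (pos, ref, alt) pair of
#' non-empty allele strings whose application to the window reproduces the
#' same edited sequence.  Used by the simulator to emit denormalized
#' spellings, and usable as an independent oracle for left-alignment
#' (it never calls [leftAlign()]).
#'
#' @param reference Reference as from [loadReference()] (or named
#'   character vector).
#' @param chrom Contig name.
#' @param start,ref,alt One spelling of the edit (1-based).
#' @param window Half-width of the enumeration window around the edit.
#' @param max_span Maximum `ref` length considered.
#' @return data.frame `pos`, `ref`, `alt` of all equivalent spellings
#'   (contig coordinates), including the input one.
#' @export
enumerateSpellings <- function(reference, chrom, start, ref, alt,
                               window = 30L, max_span = NULL) {
  clen <- if (is.character(reference)) nchar(reference[[chrom]])
          else Biostrings::width(reference)[match(chrom, names(reference))]
  ws <- max(1L, start - window)
  we <- min(clen, start + nchar(ref) - 1L + window)
  W <- refSlice(reference, chrom, ws, we)
  p0 <- start - ws + 1L                       # local coords
  E <- paste0(substr(W, 1L, p0 - 1L), alt,
              substr(W, p0 + nchar(ref), nchar(W)))
  L <- nchar(W)
  LE <- nchar(E)
  if (is.null(max_span))
    max_span <- nchar(ref) + 2L * window
  o_pos <- integer(0); o_ref <- character(0); o_alt <- character(0)
  for (pos in seq_len(L)) {
    if (pos > 1L &&
        substr(W, 1L, pos - 1L) != substr(E, 1L, pos - 1L)) break
    for (r in 0:min(max_span, L - pos + 1L)) {
      tail_len <- L - (pos + r - 1L)
      a_len <- LE - (pos - 1L) - tail_len
      if (a_len <= 0L) next
      if (r == 0L) next
      if (tail_len > 0L &&
          substr(W, pos + r, L) != substr(E, LE - tail_len + 1L, LE)) next
      rr <- substr(W, pos, pos + r - 1L)
      aa <- substr(E, pos, pos + a_len - 1L)
      if (rr == aa) next
      o_pos <- c(o_pos, ws + pos - 1L)
      o_ref <- c(o_ref, rr)
      o_alt <- c(o_alt, aa)
    }
  }
  data.frame(pos = as.integer(o_pos), ref = o_ref, alt = o_alt,
             stringsAsFactors = FALSE)
}

#' @rdname enumerateSpellings
#' @details `canonicalSpelling()` picks the canonical representation out
#'   of the enumeration by definition: minimal total allele length, then
#'   smallest position — the trimmed, anchored, leftmost form — without
#'   calling [leftAlign()].
#' @export
canonicalSpelling <- function(reference, chrom, start, ref, alt,
                              window = 30L) {
  reps <- enumerateSpellings(reference, chrom, start, ref, alt, window)
  tot <- nchar(reps$ref) + nchar(reps$alt)
  reps <- reps[tot == min(tot), , drop = FALSE]
  reps[which.min(reps$pos), , drop = FALSE]
}

rand_seq <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

`substr_set` <- function(s, at, value) {
  paste0(substr(s, 1L, at - 1L), value,
         substr(s, at + nchar(value), nchar(s)))
}

#' Simulate a multi-study cohort design
#'
#' Draws reference contigs (with homopolymer and dinucleotide repeat
#' tracts at indel sites, so left-alignment is exercised), a pool of
#' distinct variant sites, per-study membership with configurable sharing,
#' per-subpopulation allele counts (AF = AC/AN exactly), planted FILTER
#' failures, a fraction of denormalized spellings, clinical assertions
#' including contradictory pairs and pathogenic-but-common plants,
#' disease-private variants, and oversized (non-unique-key) insertions.
#' Every random draw happens here; the file writers are deterministic.
#'
#' @param seed Integer seed; one design, one stream.
#' @param n_sites Number of distinct variant sites in the pool.
#' @param contig_len Length of each of the two contigs, bp.
#' @param gc Target GC fraction of the reference.
#' @param n_disease_private Disease-cohort-exclusive plants.
#' @param n_pathogenic_common Pathogenic plants with healthy AF >= 0.02.
#' @param n_contradictory Variants asserted both pathogenic and benign by
#'   the same source.
#' @param n_unseen_clinical Asserted variants observed in no study
#'   (annotation-only records, AF bin "0").
#' @param n_long_insertion Insertions longer than [keyUniqueAltMax()].
#' @param denorm_fraction Fraction of emitted study records spelled in a
#'   non-canonical (right-shifted / padded) way.
#' @param filter_fail_fraction Fraction of (variant, study) observations
#'   failing the study's quality filters.
#' @return A `SimDesign` object carrying the full truth tables
#'   (`variants`, `freqs`, `assertions` slots).
#' @export
simDesign <- function(seed = 1L, n_sites = 220L, contig_len = 100000L,
                      gc = 0.41, n_disease_private = 10L,
                      n_pathogenic_common = 4L, n_contradictory = 4L,
                      n_unseen_clinical = 12L, n_long_insertion = 2L,
                      denorm_fraction = 0.3, filter_fail_fraction = 0.1) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  contigs <- c("1" = rand_seq(contig_len, gc),
               "2" = rand_seq(contig_len, gc))
  studies <- data.frame(
    study = c("healthyA", "healthyB", "healthyC", "diseaseD"),
    n_samples = c(2500L, 3000L, 400L, 150L),
    role = c("healthy", "healthy", "healthy", "disease"),
    incl = c(0.55, 0.45, 0.35, 0.20),
    stringsAsFactors = FALSE)
  subpops <- list(
    healthyA = c(EUR = 0.5, AFR = 0.3, EAS = 0.2),
    healthyB = c(EA = 0.6, AA = 0.4),
    healthyC = NULL,
    diseaseD = NULL)

  ## --- variant site pool: well-separated slots so 30bp enumeration
  ## windows never interact ------------------------------------------------
  n_total <- n_sites + n_unseen_clinical + n_long_insertion
  slot_gap <- 120L
  slots_per_contig <- (contig_len - 400L) %/% slot_gap
  all_slots <- rbind(
    data.frame(chrom = "1", at = 200L + slot_gap * seq_len(slots_per_contig)),
    data.frame(chrom = "2", at = 200L + slot_gap * seq_len(slots_per_contig)))
  stopifnot(nrow(all_slots) >= n_total)
  sel <- sort(sample.int(nrow(all_slots), n_total))
  sites <- all_slots[sel, , drop = FALSE]
  rownames(sites) <- NULL
  vclass <- sample(c("SNV", "INS", "DEL", "MNV"), n_total, replace = TRUE,
                   prob = c(0.60, 0.17, 0.17, 0.06))
  li_idx <- utils::tail(seq_len(n_total), n_long_insertion)
  vclass[li_idx] <- "LONGINS"
  unseen_idx <- utils::tail(setdiff(seq_len(n_total), li_idx),
                            n_unseen_clinical)

  ## --- realize each site; indel sites get a repeat tract ------------------
  vars <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    ch <- sites$chrom[i]; at <- sites$at[i]
    type <- vclass[i]
    if (type %in% c("INS", "DEL")) {
      unit <- if (stats::runif(1) < 0.5)
        sample(c("A", "C", "G", "T"), 1L)
      else paste(sample(c("A", "C", "G", "T"), 2L, replace = TRUE),
                 collapse = "")
      n_units <- sample(6:10, 1L)
      tract <- strrep(unit, n_units)
      ## anchor base before the tract, distinct from the unit's first base
      anchor <- sample(setdiff(c("A", "C", "G", "T"),
                               substr(unit, 1L, 1L)), 1L)
      contigs[[ch]] <- substr_set(contigs[[ch]], at - 1L,
                                  paste0(anchor, tract))
      if (type == "INS") {
        raw <- list(pos = at - 1L, ref = anchor, alt = paste0(anchor, unit))
      } else {
        raw <- list(pos = at - 1L, ref = paste0(anchor, unit), alt = anchor)
      }
    } else if (type == "SNV" || type == "MNV") {
      w <- if (type == "SNV") 1L else sample(2:3, 1L)
      cur <- refSlice(contigs, ch, at, at + w - 1L)
      repeat {
        new <- paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                     collapse = "")
        if (new != cur &&
            substr(new, 1L, 1L) != substr(cur, 1L, 1L) &&
            substr(new, w, w) != substr(cur, w, w)) break
      }
      raw <- list(pos = at, ref = cur, alt = new)
    } else {                                   # LONGINS: alt > unique cap
      anchor <- refSlice(contigs, ch, at, at)
      ins <- rand_seq(keyUniqueAltMax() + sample(2:40, 1L), 0.5)
      ## last inserted base must differ from the anchor so the planted
      ## spelling is already the left-aligned fixed point
      ins <- paste0(substr(ins, 1L, nchar(ins) - 1L),
                    sample(setdiff(c("A", "C", "G", "T"), anchor), 1L))
      raw <- list(pos = at, ref = anchor, alt = paste0(anchor, ins))
    }
    ## canonical truth by enumeration (independent of leftAlign)
    if (type == "LONGINS") {
      can <- data.frame(pos = raw$pos, ref = raw$ref, alt = raw$alt,
                        stringsAsFactors = FALSE)
    } else {
      can <- canonicalSpelling(contigs, ch, raw$pos, raw$ref, raw$alt)
    }
    vars[[i]] <- data.frame(
      site = i, chrom = ch, start = can$pos, ref = can$ref, alt = can$alt,
      stringsAsFactors = FALSE)
  }
  vars <- do.call(rbind, vars)

  ## --- multi-allelic sites: add a sibling SNV at some SNV positions -------
  n_multi <- 6L
  ma_pool <- setdiff(which(vclass == "SNV"), c(unseen_idx, li_idx))
  ma_idx <- sort(sample(ma_pool, min(n_multi, length(ma_pool))))
  for (i in ma_idx) {
    third <- sample(setdiff(c("A", "C", "G", "T"),
                            c(vars$ref[i], vars$alt[i])), 1L)
    vars <- rbind(vars, data.frame(
      site = nrow(vars) + 1L, chrom = vars$chrom[i], start = vars$start[i],
      ref = vars$ref[i], alt = third, stringsAsFactors = FALSE))
    vclass <- c(vclass, "SNV")
  }
  n_total <- nrow(vars)

  vars$vtype <- classifyVariant(vars$ref, vars$alt)
  vars$end <- vars$start + nchar(vars$ref) - 1L
  vars$key <- vapply(seq_len(nrow(vars)), function(i)
    encodeKey(37L, chromCode(vars$chrom[i]), vars$start[i], vars$end[i],
              vars$alt[i])$text, character(1))
  vars$unique_key <- nchar(vars$alt) <= keyUniqueAltMax()

  ## --- AF spectrum and study membership -----------------------------------
  spectrum <- sample(c("common", "lowfreq", "rare", "private"), n_total,
                     replace = TRUE, prob = c(0.15, 0.25, 0.45, 0.15))
  dp_idx <- utils::head(setdiff(which(vclass %in% c("SNV", "INS", "DEL")),
                                unseen_idx), n_disease_private)
  member <- matrix(FALSE, n_total, nrow(studies),
                   dimnames = list(NULL, studies$study))
  for (i in seq_len(n_total)) {
    if (i %in% unseen_idx) next
    if (i %in% dp_idx) { member[i, "diseaseD"] <- TRUE; next }
    if (spectrum[i] == "private") {
      member[i, sample(seq_len(nrow(studies)), 1L,
                       prob = studies$incl)] <- TRUE
    } else {
      member[i, ] <- stats::runif(nrow(studies)) < studies$incl
      if (!any(member[i, ]))
        member[i, sample.int(nrow(studies), 1L)] <- TRUE
    }
  }
  ## pathogenic-common plants live in at least one healthy study
  pc_pool <- setdiff(which(spectrum %in% c("common", "lowfreq") &
                             rowSums(member[, 1:3, drop = FALSE]) > 0),
                     c(dp_idx, unseen_idx, li_idx))
  pc_idx <- utils::head(pc_pool, n_pathogenic_common)

  ## --- per-(variant, study, subpop) allele counts -------------------------
  af_target <- numeric(n_total)
  af_target[spectrum == "common"] <- stats::runif(sum(spectrum == "common"),
                                                  0.05, 0.5)
  af_target[spectrum == "lowfreq"] <- stats::runif(sum(spectrum == "lowfreq"),
                                                   0.005, 0.05)
  af_target[spectrum == "rare"] <- stats::runif(sum(spectrum == "rare"),
                                                0.0005, 0.005)
  af_target[spectrum == "private"] <- 0          # AC set directly
  af_target[pc_idx] <- stats::runif(length(pc_idx), 0.02, 0.2)

  freqs <- vector("list", n_total * nrow(studies))
  nf <- 0L
  for (i in seq_len(n_total)) {
    for (s in seq_len(nrow(studies))) {
      if (!member[i, s]) next
      st <- studies$study[s]
      sp <- subpops[[st]]
      if (is.null(sp)) {
        an <- 2L * studies$n_samples[s]
        ac <- if (spectrum[i] == "private" || i %in% dp_idx)
          sample(1:3, 1L) else max(1L, round(af_target[i] * an))
        tab <- data.frame(subpop = "ALL", AC = ac, AN = an)
      } else {
        an <- round(2L * studies$n_samples[s] * sp)
        jit <- stats::runif(length(sp), 0.5, 1.5)
        ac <- if (spectrum[i] == "private")
          as.integer(seq_along(sp) == which.max(sp))
        else round(af_target[i] * jit * an)
        if (all(ac == 0)) ac[which.max(sp)] <- 1L
        tab <- data.frame(subpop = names(sp), AC = as.integer(ac),
                          AN = as.integer(an))
        tab <- rbind(tab, data.frame(subpop = "ALL", AC = sum(tab$AC),
                                     AN = sum(tab$AN)))
      }
      nf <- nf + 1L
      freqs[[nf]] <- data.frame(site = i, study = st, subpop = tab$subpop,
                                AC = tab$AC, AN = tab$AN,
                                AF = tab$AC / tab$AN,
                                stringsAsFactors = FALSE)
    }
  }
  freqs <- do.call(rbind, freqs[seq_len(nf)])

  ## --- pass flags and emitted spellings ------------------------------------
  obs <- unique(freqs[c("site", "study")])
  obs$passed <- stats::runif(nrow(obs)) >= filter_fail_fraction
  obs$emit_pos <- vars$start[obs$site]
  obs$emit_ref <- vars$ref[obs$site]
  obs$emit_alt <- vars$alt[obs$site]
  for (j in seq_len(nrow(obs))) {
    i <- obs$site[j]
    if (vclass[i] == "LONGINS") next
    if (stats::runif(1) >= denorm_fraction) next
    reps <- enumerateSpellings(contigs, vars$chrom[i], vars$start[i],
                               vars$ref[i], vars$alt[i], window = 12L)
    reps <- reps[!(reps$pos == vars$start[i] & reps$ref == vars$ref[i] &
                     reps$alt == vars$alt[i]), , drop = FALSE]
    reps <- reps[nchar(reps$ref) + nchar(reps$alt) <=
                   nchar(vars$ref[i]) + nchar(vars$alt[i]) + 8L, ,
                 drop = FALSE]
    if (!nrow(reps)) next
    pick <- reps[sample.int(nrow(reps), 1L), ]
    obs$emit_pos[j] <- pick$pos
    obs$emit_ref[j] <- pick$ref
    obs$emit_alt[j] <- pick$alt
  }

  ## --- clinical assertions --------------------------------------------------
  src <- "clindb"
  observed_idx <- setdiff(which(rowSums(member) > 0), li_idx)
  path_seen <- utils::head(setdiff(observed_idx,
                                   c(pc_idx, dp_idx)), 20L)
  asr <- list(
    data.frame(site = pc_idx, source = src, significance = "pathogenic",
               stringsAsFactors = FALSE),
    data.frame(site = path_seen, source = src,
               significance = sample(c("pathogenic", "likely_pathogenic",
                                       "benign", "likely_benign", "VUS",
                                       "risk_factor", "other"),
                                     length(path_seen), replace = TRUE),
               stringsAsFactors = FALSE),
    data.frame(site = unseen_idx, source = src,
               significance = sample(c("pathogenic", "likely_pathogenic",
                                       "VUS"), length(unseen_idx),
                                     replace = TRUE,
                                     prob = c(0.6, 0.2, 0.2)),
               stringsAsFactors = FALSE))
  asr <- do.call(rbind, asr)
  ## contradictions: both a pathogenic and a benign label from one source
  ct_idx <- utils::head(setdiff(observed_idx, c(pc_idx, dp_idx, path_seen)),
                        n_contradictory)
  asr <- rbind(asr,
    data.frame(site = rep(ct_idx, 2L), source = src,
               significance = rep(c("pathogenic", "benign"),
                                  each = length(ct_idx)),
               stringsAsFactors = FALSE))
  asr <- asr[!duplicated(asr), , drop = FALSE]
  asr$chrom <- vars$chrom[asr$site]
  asr$pos <- vars$start[asr$site]
  asr$ref <- vars$ref[asr$site]
  asr$alt <- vars$alt[asr$site]
  asr$key <- vars$key[asr$site]
  rownames(asr) <- NULL

  vars$spectrum <- spectrum
  vars$class <- vclass
  vars$disease_private <- seq_len(n_total) %in% dp_idx
  vars$pathogenic_common <- seq_len(n_total) %in% pc_idx
  vars$unseen <- seq_len(n_total) %in% unseen_idx
  for (st in studies$study) {
    vars[[paste0("in_", st)]] <- member[, st]
    vars[[paste0("passed_", st)]] <- NA
    m <- obs$study == st
    vars[[paste0("passed_", st)]][obs$site[m]] <- obs$passed[m]
  }

  methods::new("SimDesign", seed = as.integer(seed), contigs = contigs,
               studies = studies, subpops = subpops, variants = vars,
               freqs = merge(freqs, obs[c("site", "study", "passed",
                                          "emit_pos", "emit_ref",
                                          "emit_alt")],
                             by = c("site", "study"), sort = FALSE),
               assertions = asr,
               params = list(gc = gc, denorm_fraction = denorm_fraction,
                             filter_fail_fraction = filter_fail_fraction))
}

#' Write the simulated reference as FASTA
#'
#' @param design A [simDesign()] object.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
makeReference <- function(design, path) {
  dna <- Biostrings::DNAStringSet(design@contigs)
  names(dna) <- names(design@contigs)
  Biostrings::writeXStringSet(dna, path, width = 70L)
  invisible(path)
}

fmt_af <- function(af) {
  sub("\\.?0+$", "", formatC(af, format = "f", digits = 10))
}

#' Write one simulated study as a VCF
#'
#' Renders the study's observations (with their possibly denormalized
#' spellings and planted FILTER failures) as a VCF 4.2 file with
#' per-subpopulation `AC_<POP>/AN_<POP>/AF_<POP>` INFO fields plus overall
#' `AC/AN/AF`.  Canonical SNVs sharing an emitted (pos, ref) are merged
#' into multi-allelic records.
#'
#' @param design A [simDesign()] object.
#' @param study_id One of the design's study labels.
#' @param path Output VCF path.
#' @return Invisibly, `path`.
#' @export
makeStudyVcf <- function(design, study_id, path) {
  stopifnot(study_id %in% design@studies$study)
  fr <- design@freqs[design@freqs$study == study_id, , drop = FALSE]
  sp <- design@subpops[[study_id]]
  pops <- names(sp)
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", names(design@contigs), ",length=",
           nchar(design@contigs), ">"),
    '##FILTER=<ID=q10,Description="Low quality">',
    '##INFO=<ID=AC,Number=A,Type=Integer,Description="Allele count">',
    '##INFO=<ID=AN,Number=1,Type=Integer,Description="Allele number">',
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">')
  for (p in pops) hdr <- c(hdr,
    paste0('##INFO=<ID=AC_', p, ',Number=A,Type=Integer,Description="',
           p, ' allele count">'),
    paste0('##INFO=<ID=AN_', p, ',Number=1,Type=Integer,Description="',
           p, ' allele number">'),
    paste0('##INFO=<ID=AF_', p, ',Number=A,Type=Float,Description="',
           p, ' allele frequency">'))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", sep = "\t"))
  sites <- unique(fr[c("site", "emit_pos", "emit_ref", "emit_alt",
                       "passed")])
  sites$chrom <- design@variants$chrom[sites$site]
  ## merge canonical SNVs sharing (chrom, pos, ref) into one record; the
  ## FILTER column is per record, so only siblings with equal pass flags
  ## are merged
  grp <- paste(sites$chrom, sites$emit_pos, sites$emit_ref, sites$passed)
  can_snv <- nchar(sites$emit_ref) == 1L & nchar(sites$emit_alt) == 1L
  grp[!can_snv] <- paste0(grp[!can_snv], "#", sites$site[!can_snv])
  recs <- lapply(split(seq_len(nrow(sites)), grp), function(ix) {
    ix <- ix[order(sites$emit_alt[ix])]
    s <- sites[ix, , drop = FALSE]
    info_of <- function(pop, field) {
      vapply(s$site, function(v) {
        r <- fr[fr$site == v & fr$subpop == pop, , drop = FALSE]
        if (!nrow(r)) NA_character_
        else if (field == "AF") fmt_af(r$AF) else as.character(r[[field]])
      }, character(1))
    }
    all_pops <- c("ALL", pops)
    parts <- character(0)
    for (p in all_pops) {
      tagp <- if (p == "ALL") "" else paste0("_", p)
      ac <- info_of(p, "AC"); an <- info_of(p, "AN"); af <- info_of(p, "AF")
      if (all(is.na(ac))) next
      parts <- c(parts,
                 paste0("AC", tagp, "=", paste(ac, collapse = ",")),
                 paste0("AN", tagp, "=", an[!is.na(an)][1L]),
                 paste0("AF", tagp, "=", paste(af, collapse = ",")))
    }
    list(chrom = s$chrom[1L], pos = s$emit_pos[1L],
         line = paste(s$chrom[1L], s$emit_pos[1L], ".", s$emit_ref[1L],
                      paste(s$emit_alt, collapse = ","), ".",
                      if (all(!s$passed)) "q10" else "PASS",
                      paste(parts, collapse = ";"), sep = "\t"))
  })
  ord <- order(vapply(recs, `[[`, character(1), "chrom"),
               vapply(recs, `[[`, numeric(1), "pos"))
  writeLines(c(hdr, vapply(recs[ord], `[[`, character(1), "line")), path)
  invisible(path)
}

#' Write the simulated clinical assertion table
#'
#' TSV with columns `chrom`, `pos`, `ref`, `alt`, `source`,
#' `significance`, one row per assertion (contradictory pairs appear as
#' two rows).
#'
#' @param design A [simDesign()] object.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
makeClinicalTable <- function(design, path) {
  a <- design@assertions[c("chrom", "pos", "ref", "alt", "source",
                           "significance")]
  utils::write.table(a, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render every file of a design
#'
#' Writes `reference.fa`, one `<study>.vcf` per study, and
#' `clinical.tsv` into a directory.
#'
#' @param design A [simDesign()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
simulateAll <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(reference = file.path(dir, "reference.fa"),
                clinical = file.path(dir, "clinical.tsv"))
  makeReference(design, paths$reference)
  makeClinicalTable(design, paths$clinical)
  for (st in design@studies$study) {
    p <- file.path(dir, paste0(st, ".vcf"))
    makeStudyVcf(design, st, p)
    paths[[st]] <- p
  }
  invisible(paths)
}

#' Ingest every simulated study into a fresh registry
#'
#' Convenience for tests and examples: renders the design to `dir`,
#' ingests each study VCF, and imports the clinical table as `phenotype`
#' annotations.
#'
#' @param design A [simDesign()] object.
#' @param dir Working directory for the rendered files.
#' @return A populated [VariantRegistry].
#' @export
ingestDesign <- function(design, dir = tempfile("sim")) {
  paths <- simulateAll(design, dir)
  reference <- loadReference(paths$reference)
  reg <- newRegistry(37L)
  for (st in design@studies$study) {
    sp <- names(design@subpops[[st]])
    ingestStudy(reg, paths[[st]], st, reference,
                subpopFieldMap(if (is.null(sp)) character() else sp))
  }
  clin <- utils::read.table(paths$clinical, sep = "\t", header = TRUE,
                            colClasses = c("character", "integer",
                                           "character", "character",
                                           "character", "character"))
  clin$label <- clin$significance
  importAnnotations(reg, clin, "phenotype", reference)
  reg
}
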