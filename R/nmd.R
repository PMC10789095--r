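# Protein-truncating variants: ClinVar-style filtering, premature termination
# codon (PTC) derivation for nonsense and frameshift alleles, and the
# four-rule classifier for PTCs that escape nonsense-mediated decay (NMD).

PLP_TERMS <- c("Pathogenic", "Likely pathogenic", "Pathogenic/Likely pathogenic")
KNOWN_SIGNIFICANCE <- c(
  PLP_TERMS, "Benign", "Likely benign", "Benign/Likely benign",
  "Uncertain significance", "Conflicting interpretations of pathogenicity",
  "risk factor", "drug response", "association", "protective", "other",
  "not provided")

#' ClinVar-style pathogenic-variant filter
#'
#' Keeps rows that are (1) pathogenic or likely pathogenic, (2) free of
#' conflicting interpretations, and (3) reviewed with one or more gold stars.
#' In `"cnv-loss"` mode the consequence must additionally be
#' `"copy number loss"`. Rows with a clinical-significance term outside the
#' known vocabulary are dropped with a warning, never silently kept. The
#' filter is idempotent.
#'
#' @param variants Data frame with columns `clinical_significance`,
#'   `review_stars`, `has_conflicts` (and `consequence` for CNV mode).
#' @param kind `"short-variant"` or `"cnv-loss"`.
#' @return The filtered tibble.
#' @export
filter_pathogenic <- function(variants, kind = c("short-variant", "cnv-loss")) {
  kind <- match.arg(kind)
  unknown <- !variants$clinical_significance %in% KNOWN_SIGNIFICANCE
  if (any(unknown)) {
    rlang::warn(sprintf(
      "dropping %d row(s) with unknown clinical significance term(s): %s",
      sum(unknown),
      paste(unique(variants$clinical_significance[unknown]), collapse = ", ")))
  }
  keep <- variants$clinical_significance %in% PLP_TERMS &
    !is.na(variants$has_conflicts) & !variants$has_conflicts &
    !is.na(variants$review_stars) & variants$review_stars >= 1
  if (kind == "cnv-loss") {
    keep <- keep & variants$consequence == "copy number loss"
  }
  tibble::as_tibble(variants[keep & !unknown, , drop = FALSE])
}

#' Classify a consequence term into a PTV class
#'
#' Maps the SnpEff-style vocabulary: `stop_gained` to nonsense,
#' `frameshift_variant` to frameshift, `splice_region_variant` to splice;
#' everything else is `not-ptv`.
#'
#' @param consequence Character vector of consequence terms.
#' @return Character vector over `nonsense`, `frameshift`, `splice`,
#'   `not-ptv`.
#' @export
classify_ptv <- function(consequence) {
  dplyr::case_when(
    consequence == "stop_gained" ~ "nonsense",
    consequence == "frameshift_variant" ~ "frameshift",
    consequence == "splice_region_variant" ~ "splice",
    TRUE ~ "not-ptv")
}

apply_indel <- function(cdna, pos, ref, alt) {
  if (substr(cdna, pos, pos + nchar(ref) - 1L) != ref) {
    abort_ps(sprintf("ref allele '%s' does not match the cDNA at position %d",
                     ref, pos), "psdosage_validation_error")
  }
  paste0(substr(cdna, 1L, pos - 1L), alt,
         substr(cdna, pos + nchar(ref), nchar(cdna)))
}

first_stop_from <- function(cdna, cds_start) {
  L <- nchar(cdna)
  starts <- seq(cds_start, L - 2L, by = 3L)
  if (length(starts) == 0) return(NA_integer_)
  codons <- substring(cdna, starts, starts + 2L)
  hit <- which(codons %in% STOP_CODONS)
  if (length(hit) == 0) NA_integer_ else starts[hit[1]]
}

#' PTC position for a nonsense substitution
#'
#' The PTC coordinate is the first nucleotide of the affected codon, 1-based
#' on the cDNA: `cds_start + 3 * floor((cdna_pos - cds_start) / 3)`. When the
#' transcript sequence is available the substituted codon is verified to be a
#' stop codon.
#'
#' @param cdna_pos 1-based cDNA position of the substitution.
#' @param cds_start 1-based cDNA position of the first nucleotide of the
#'   start codon.
#' @param cdna Optional transcript sequence for validation.
#' @param ref,alt Optional alleles (single nucleotides), used with `cdna`.
#' @return Integer PTC position.
#' @export
ptc_from_nonsense <- function(cdna_pos, cds_start, cdna = NULL,
                              ref = NULL, alt = NULL) {
  if (is.na(cds_start)) {
    abort_ps("cds_start is required to derive a PTC", "psdosage_validation_error")
  }
  if (cdna_pos < cds_start) {
    abort_ps("variant position is upstream of the start codon",
             "psdosage_validation_error")
  }
  ptc <- cds_start + 3L * ((cdna_pos - cds_start) %/% 3L)
  if (!is.null(cdna) && !is.null(ref) && !is.null(alt)) {
    mutated <- apply_indel(cdna, cdna_pos, ref, alt)
    codon <- substr(mutated, ptc, ptc + 2L)
    if (!codon %in% STOP_CODONS) {
      abort_ps(sprintf(
        "substituted codon '%s' at cDNA %d is not a stop codon", codon, ptc),
        "psdosage_validation_error")
    }
  }
  ptc
}

#' PTC position for a frameshift indel
#'
#' Applies the indel to the cDNA, translates codon by codon from the start
#' codon in the shifted frame, and reports the first stop codon encountered.
#' Positions upstream of the indel are identical in original and mutated
#' coordinates; a stop at or downstream of the indel is reported in
#' mutated-cDNA coordinates and flagged as such. A frame-preserving indel
#' (length difference a multiple of 3) is rejected; a shifted frame with no
#' downstream stop returns status `"no_stop"`.
#'
#' @param cdna_pos 1-based cDNA position where `ref` is replaced by `alt`.
#' @param ref,alt Allele strings anchored at `cdna_pos` (lengths must differ
#'   by a non-multiple of 3).
#' @param cds_start 1-based cDNA position of the start codon.
#' @param cdna Transcript sequence.
#' @return List with `ptc_cdna_pos`, `coords` (`"original"` or `"mutated"`),
#'   and `status` (`"ok"` or `"no_stop"`).
#' @export
ptc_from_frameshift <- function(cdna_pos, ref, alt, cds_start, cdna) {
  if (is.na(cds_start) || is.null(cdna) || is.na(cdna)) {
    abort_ps("frameshift PTC derivation needs cds_start and the cDNA sequence",
             "psdosage_validation_error")
  }
  shift <- nchar(alt) - nchar(ref)
  if (shift %% 3L == 0L) {
    abort_ps("in-frame indel (length difference a multiple of 3) is not a frameshift",
             "psdosage_validation_error")
  }
  mutated <- apply_indel(cdna, cdna_pos, ref, alt)
  stop_pos <- first_stop_from(mutated, cds_start)
  if (is.na(stop_pos)) {
    return(list(ptc_cdna_pos = NA_integer_, coords = NA_character_,
                status = "no_stop"))
  }
  if (stop_pos + 2L < cdna_pos) {
    list(ptc_cdna_pos = stop_pos, coords = "original", status = "ok")
  } else {
    list(ptc_cdna_pos = stop_pos, coords = "mutated", status = "ok")
  }
}

NMD_RULES <- c("last_exon", "penultimate_last50", "start_proximal_lt150",
               "long_exon_gt400")

#' Four-rule NMD-escape classification of a PTC
#'
#' A premature termination codon escapes nonsense-mediated decay when any of
#' the following holds on the cDNA: (1) the PTC lies in the last exon; (2) it
#' lies in the last 50 nt (inclusive) of the penultimate exon; (3) it is
#' fewer than 150 nt downstream of the first nucleotide of the start codon
#' (strict); (4) its exon is longer than 400 nt (strict). The rules combine
#' by OR and every firing rule is reported. A single-exon transcript fires
#' rule 1 by construction.
#'
#' @param ptc_cdna_pos Integer vector of PTC positions (first nucleotide of
#'   the stop codon, 1-based on the cDNA).
#' @param exon_lengths Integer vector of exon lengths, 5'->3' in transcript
#'   orientation.
#' @param cds_start 1-based cDNA start-codon position; may be `NA` when the
#'   verdict is decidable from the other rules alone.
#' @return Tibble with one row per PTC: the four rule flags, `escaping`, and
#'   `rules` (comma-separated names of firing rules).
#' @export
classify_nmd <- function(ptc_cdna_pos, exon_lengths, cds_start = NA) {
  cum <- cumsum(as.numeric(exon_lengths))
  total <- cum[length(cum)]
  n_ex <- length(exon_lengths)
  if (any(ptc_cdna_pos < 1 | ptc_cdna_pos > total - 2)) {
    abort_ps("PTC position outside the cDNA (must leave room for a stop codon)",
             "psdosage_validation_error")
  }
  exon_of <- findInterval(ptc_cdna_pos - 1, c(0, cum[-n_ex]))
  r1 <- exon_of == n_ex
  r2 <- rep(FALSE, length(ptc_cdna_pos))
  if (n_ex >= 2) {
    pen_end <- cum[n_ex - 1L]
    pen_start <- if (n_ex >= 3) cum[n_ex - 2L] + 1 else 1
    lo <- max(pen_start, pen_end - 49)
    r2 <- ptc_cdna_pos >= lo & ptc_cdna_pos <= pen_end
  }
  r4 <- exon_lengths[exon_of] > 400
  if (is.na(cds_start)) {
    if (any(!(r1 | r2 | r4))) {
      abort_ps("cds_start is required: verdict depends on the start-proximity rule",
               "psdosage_validation_error")
    }
    r3 <- rep(NA, length(ptc_cdna_pos))
  } else {
    r3 <- (ptc_cdna_pos - cds_start) < 150
  }
  esc <- r1 | r2 | (!is.na(r3) & r3) | r4
  rules <- vapply(seq_along(ptc_cdna_pos), function(i) {
    fired <- NMD_RULES[c(r1[i], r2[i], isTRUE(r3[i]), r4[i])]
    paste(fired, collapse = ",")
  }, "")
  tibble::tibble(
    ptc_cdna_pos = as.integer(ptc_cdna_pos),
    last_exon = r1, penultimate_last50 = r2,
    start_proximal_lt150 = r3, long_exon_gt400 = r4,
    escaping = esc, rules = rules)
}

#' Classify a variant table end to end
#'
#' For each variant: determines the PTV class, derives the PTC for nonsense
#' and frameshift alleles from the matching gene model, applies the
#' NMD-escape rules, and reports truncation bookkeeping (first lost residue
#' and lost fraction of the wild-type protein) where the transcript sequence
#' allows it. Splice-disrupting PTVs have no defined transcript outcome and
#' are reported as `NMD-undetermined`; frameshifts with no downstream stop
#' are reported as `no_stop` and excluded from the NMD verdict.
#'
#' @param variants Variant tibble (schema `"variants"`).
#' @param models Gene-model tibble from [read_gene_models()].
#' @return Tibble with one row per variant: `ptv_class`, `ptc_cdna_pos`,
#'   `ptc_coords`, `status`, `escaping`, `rules`, `first_lost_residue`,
#'   `trunc_fraction`.
#' @export
nmd_classify_variants <- function(variants, models) {
  res <- purrr::pmap(variants, function(...) {
    v <- list(...)
    cls <- classify_ptv(v$consequence)
    base <- tibble::tibble(
      gene_id = v$gene_id, transcript_id = v$transcript_id,
      cdna_pos = v$cdna_pos, ptv_class = cls,
      ptc_cdna_pos = NA_integer_, ptc_coords = NA_character_,
      status = NA_character_, escaping = NA, rules = NA_character_,
      first_lost_residue = NA_integer_, trunc_fraction = NA_real_)
    if (cls == "not-ptv") {
      base$status <- "not-ptv"
      return(base)
    }
    if (cls == "splice") {
      base$status <- "NMD-undetermined"
      return(base)
    }
    m <- models[models$transcript_id == v$transcript_id, ]
    if (nrow(m) == 0) {
      base$status <- "no-model"
      return(base)
    }
    exl <- m$exon_lengths[[1]]
    if (cls == "nonsense") {
      ptc <- ptc_from_nonsense(v$cdna_pos, m$cds_start, m$cdna, v$ref, v$alt)
      coords <- "original"
    } else {
      fs <- ptc_from_frameshift(v$cdna_pos, v$ref, v$alt, m$cds_start, m$cdna)
      if (fs$status == "no_stop") {
        base$status <- "no_stop"
        return(base)
      }
      ptc <- fs$ptc_cdna_pos
      coords <- fs$coords
    }
    ver <- classify_nmd(ptc, exl, m$cds_start)
    base$ptc_cdna_pos <- ptc
    base$ptc_coords <- coords
    base$status <- "ok"
    base$escaping <- ver$escaping
    base$rules <- ver$rules
    if (!is.na(m$cdna)) {
      wt_stop <- first_stop_from(m$cdna, m$cds_start)
      if (!is.na(wt_stop)) {
        prot_len <- (wt_stop - m$cds_start) %/% 3L
        first_lost <- (ptc - m$cds_start) %/% 3L + 1L
        if (first_lost >= 1 && first_lost <= prot_len) {
          base$first_lost_residue <- as.integer(first_lost)
          base$trunc_fraction <- (prot_len - first_lost + 1) / prot_len
        }
      }
    }
    base
  })
  dplyr::bind_rows(res)
}
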