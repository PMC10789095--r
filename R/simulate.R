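# Seeded synthetic-data generators. Every generator is a pure function of
# its arguments plus the seed, so reruns are byte-identical; the planted
# structure (composition profiles, effect sizes, dataset sizes) mirrors the
# statistical shape of the curated phase-separation datasets the toolkit is
# meant to analyse: disordered, low-complexity, charge-blocky positives
# against folded, hydrophobic negatives, 93 positive regions with negatives
# at 56 remainder + 2x93 sampled, and 53+70 vs 282 protein training sets.

# Residue profiles. The PS-like profile is enriched in D,E,K,R,G,S,Q,P
# (charged + disorder-promoting); the folded-like profile follows a globular
# hydrophobic composition.
PS_PROFILE <- c(
  A = 0.04, D = 0.12, E = 0.12, G = 0.14, K = 0.10, N = 0.04, P = 0.08,
  Q = 0.10, R = 0.08, S = 0.14, T = 0.04)
FOLDED_PROFILE <- c(
  A = 0.09, C = 0.02, D = 0.04, E = 0.04, F = 0.05, G = 0.06, H = 0.02,
  I = 0.08, K = 0.04, L = 0.12, M = 0.03, N = 0.03, P = 0.03, Q = 0.03,
  R = 0.04, S = 0.05, T = 0.05, V = 0.09, W = 0.02, Y = 0.04)

mix_profile <- function(w) {
  all_aa <- union(names(PS_PROFILE), names(FOLDED_PROFILE))
  ps <- stats::setNames(rep(0, length(all_aa)), all_aa)
  fo <- ps
  ps[names(PS_PROFILE)] <- PS_PROFILE
  fo[names(FOLDED_PROFILE)] <- FOLDED_PROFILE
  w * ps + (1 - w) * fo
}

sample_stretch <- function(n, w) {
  pr <- mix_profile(w)
  sample(names(pr), n, replace = TRUE, prob = pr)
}

# Rearrange the charged residues of a stretch into alternating-sign blocks,
# raising kappa without changing composition (the blocky charge layout of
# many phase-separating IDRs).
blockify_charges <- function(chars) {
  charged <- which(chars %in% c("D", "E", "K", "R"))
  if (length(charged) < 4) return(chars)
  pos_pool <- chars[charged][chars[charged] %in% c("K", "R")]
  neg_pool <- chars[charged][chars[charged] %in% c("D", "E")]
  seq_out <- character(0)
  take_pos <- length(pos_pool) >= length(neg_pool)
  while (length(pos_pool) + length(neg_pool) > 0) {
    blk <- 3L + stats::rgeom(1, 0.35)
    if ((take_pos || length(neg_pool) == 0) && length(pos_pool) > 0) {
      k <- min(blk, length(pos_pool))
      seq_out <- c(seq_out, pos_pool[seq_len(k)])
      pos_pool <- pos_pool[-seq_len(k)]
    } else {
      k <- min(blk, length(neg_pool))
      seq_out <- c(seq_out, neg_pool[seq_len(k)])
      neg_pool <- neg_pool[-seq_len(k)]
    }
    take_pos <- !take_pos
  }
  chars[charged] <- seq_out
  chars
}

# A disordered low-complexity stretch: mixture composition, blocky charges,
# and (optionally) an embedded homopolymer run.
idr_stretch <- function(n, w, run_prob = 0.6, run_range = c(8, 18)) {
  chars <- blockify_charges(sample_stretch(n, w))
  if (stats::runif(1) < run_prob && n > run_range[2] + 4) {
    rl <- sample(run_range[1]:run_range[2], 1)
    at <- sample.int(n - rl, 1)
    chars[at:(at + rl - 1L)] <- sample(c("Q", "G", "S", "P"), 1)
  }
  chars
}

#' Simulate a labelled protein set
#'
#' Phase-separation-like proteins carry at least one disordered,
#' low-complexity, charge-blocky stretch on a folded backbone; non-PS
#' proteins are drawn entirely from the folded hydrophobic profile. Lengths
#' are log-normal with median about 400 residues.
#'
#' @param n_ps,n_nonps Number of proteins per class.
#' @param seed Integer seed.
#' @return List with `proteins` (tibble `id`, `sequence`) and `labels`
#'   (tibble `id`, `class`).
#' @export
simulate_protein_set <- function(n_ps, n_nonps, seed = 1) {
  withr::with_seed(derive_seed(seed, 21L), {
    lens <- pmax(80L, pmin(2000L, round(stats::rlnorm(n_ps + n_nonps,
                                                      log(400), 0.35))))
    make_one <- function(i) {
      L <- lens[i]
      if (i <= n_ps) {
        idr_len <- round(stats::runif(1, 0.25, 0.55) * L)
        at <- sample.int(L - idr_len + 1L, 1)
        chars <- sample_stretch(L, 0.05)
        chars[at:(at + idr_len - 1L)] <-
          idr_stretch(idr_len, stats::runif(1, 0.75, 0.95))
        paste(chars, collapse = "")
      } else {
        paste(sample_stretch(L, 0.02), collapse = "")
      }
    }
    seqs <- vapply(seq_len(n_ps + n_nonps), make_one, "")
    ids <- c(sprintf("PSP%03d", seq_len(n_ps)),
             sprintf("NPS%03d", seq_len(n_nonps)))
    list(proteins = tibble::tibble(id = ids, sequence = seqs),
         labels = tibble::tibble(
           id = ids, class = rep(c("PS", "non-PS"), c(n_ps, n_nonps))))
  })
}

#' Simulate the region benchmark
#'
#' Emulates the curated region data: `n_pos` positive phase-separating
#' regions (disorder/low-complexity-rich, length > 20), negatives formed by
#' the remainder regions of the same PS-like proteins (length > 20; about
#' 56/93 of the positive count, the curation ratio) plus `2 * n_pos` regions
#' sampled from non-PS proteins according to the positive length
#' distribution. Class separation is driven by a latent "PS-ness" mixture
#' weight with overlapping distributions per class, so no single composition
#' feature separates the classes perfectly.
#'
#' @param n_pos Number of positive regions (default 93).
#' @param seed Integer seed.
#' @return List with `regions` (tibble with `protein_id`, `start`, `end`,
#'   `label`, `source`), `proteins`, and `positive_lengths`.
#' @export
simulate_region_dataset <- function(n_pos = 93, seed = 1) {
  if (n_pos < 5) abort_ps("n_pos must be >= 5", "psdosage_validation_error")
  n_rem <- round(56 / 93 * n_pos)
  withr::with_seed(derive_seed(seed, 22L), {
    pos_len <- pmax(25L, pmin(220L, round(stats::rlnorm(n_pos, log(70), 0.45))))
    rows <- vector("list", n_pos)
    prot <- vector("list", n_pos)
    for (i in seq_len(n_pos)) {
      w_pos <- stats::rbeta(1, 5, 2)
      flank_len <- if (i <= n_rem) sample(30:150, 1) else sample(3:12, 1)
      w_fl <- stats::rbeta(1, 2.5, 3.5)
      flank <- sample_stretch(flank_len, w_fl)
      if (w_fl > 0.45 && flank_len > 30 && stats::runif(1) < 0.25) {
        flank <- idr_stretch(flank_len, w_fl, run_prob = 0.4,
                             run_range = c(6, 10))
      }
      core <- idr_stretch(pos_len[i], w_pos)
      at_start <- stats::runif(1) < 0.5
      chars <- if (at_start) c(core, flank) else c(flank, core)
      id <- sprintf("PSR%03d", i)
      prot[[i]] <- tibble::tibble(id = id,
                                  sequence = paste(chars, collapse = ""))
      pos_start <- if (at_start) 1L else flank_len + 1L
      reg <- tibble::tibble(
        protein_id = id, start = pos_start,
        end = pos_start + pos_len[i] - 1L,
        label = "positive", source = "curated-positive")
      if (flank_len > 20) {
        fl_start <- if (at_start) pos_len[i] + 1L else 1L
        reg <- dplyr::bind_rows(reg, tibble::tibble(
          protein_id = id, start = fl_start,
          end = fl_start + flank_len - 1L,
          label = "negative", source = "ps-protein-remainder"))
      }
      rows[[i]] <- reg
    }
    nonps_n <- max(20L, ceiling(n_pos / 3))
    nonps <- tibble::tibble(
      id = sprintf("NPR%03d", seq_len(nonps_n)),
      sequence = vapply(seq_len(nonps_n), function(i) {
        paste(sample_stretch(sample(300:800, 1), stats::rbeta(1, 1.5, 6)),
              collapse = "")
      }, ""))
    regions <- dplyr::bind_rows(rows)
    sampled <- sample_negative_regions(nonps, pos_len, ratio = 2,
                                       seed = derive_seed(seed, 23L))
    list(regions = dplyr::bind_rows(regions, sampled),
         proteins = dplyr::bind_rows(dplyr::bind_rows(prot), nonps),
         positive_lengths = pos_len)
  })
}

#' Designed protein for the truncation-sweep check
#'
#' A fully deterministic protein built for the score-vs-truncation-length
#' comparison: a short folded N-terminal cap, then a long
#' phase-separation-prone disordered core occupying the C-terminal body of
#' the protein (a low-entropy G/S/Q motif with balanced, blocky K and D
#' charge runs), whose PS character relaxes over the final `decay` residues
#' by deterministically interleaving hydrophobic residues at an increasing
#' rate toward the extreme C-terminus. Because the distal tail is the
#' weakest part of the PS region, the suffix lost by a truncation becomes
#' steadily more PS-like as the truncation point moves toward the
#' N-terminus, so a sound truncation scorer should produce scores that
#' increase with lost length. The sequence contains no randomness: the
#' design is a fixture, not a draw.
#'
#' @param length Total protein length.
#' @param cap Folded cap length at the N-terminus.
#' @param decay Length of the graded C-terminal tail.
#' @return One-row tibble with `id`, `sequence`.
#' @export
simulate_truncation_protein <- function(length = 400, cap = 30, decay = 120) {
  capseq <- rep(strsplit("LIVAFMLTVW", "")[[1]], length.out = cap)
  n_idr <- length - cap
  n_plat <- n_idr - decay
  motif <- strsplit("GSKKKQSSGQQDDDSGSQQSG", "")[[1]]
  plat <- rep(motif, length.out = n_plat)
  dec <- rep(motif, length.out = decay)
  hydro <- strsplit("LIVAFMWCTY", "")[[1]]
  for (i in seq_len(decay)) {
    # golden-ratio low-discrepancy rule: hydrophobic substitution rate ramps
    # linearly toward the C-terminus without any RNG
    if ((i * 0.618034) %% 1 < i / decay) {
      dec[i] <- hydro[1 + (i %% base::length(hydro))]
    }
  }
  tibble::tibble(id = "TRUNC_DESIGN",
                 sequence = paste(c(capseq, plat, dec), collapse = ""))
}

# --- gene models + variants --------------------------------------------------

NON_STOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  STOP_CODONS)

# Literal transcription of the four published NMD-escape rules, kept as an
# independent reference implementation for truth tables and
# dual-implementation tests.
#' Reference re-evaluation of the NMD-escape rules
#'
#' A deliberately plain, loop-based transcription of the four rules (last
#' exon; last 50 nt of the penultimate exon; < 150 nt from the start codon;
#' exon longer than 400 nt), independent of [classify_nmd()]. Used to build
#' ground-truth tables for simulated variants and as the second
#' implementation in agreement tests.
#'
#' @param ptc_cdna_pos Single PTC position (1-based cDNA).
#' @param exon_lengths Exon lengths 5'->3'.
#' @param cds_start Start-codon cDNA position.
#' @return List with `escaping` and `rules` (character vector).
#' @export
nmd_rules_reference <- function(ptc_cdna_pos, exon_lengths, cds_start) {
  # locate the exon containing the PTC by walking exons 5'->3'
  exon_idx <- 0L
  upstream <- 0L
  for (i in seq_along(exon_lengths)) {
    if (ptc_cdna_pos <= upstream + exon_lengths[i]) {
      exon_idx <- i
      break
    }
    upstream <- upstream + exon_lengths[i]
  }
  rules <- character(0)
  # (1) PTC in the last exon
  if (exon_idx == length(exon_lengths)) rules <- c(rules, "last_exon")
  # (2) PTC in the last 50 nt of the penultimate exon
  if (length(exon_lengths) >= 2 && exon_idx == length(exon_lengths) - 1L) {
    pen_end <- sum(exon_lengths[seq_len(length(exon_lengths) - 1L)])
    if (pen_end - ptc_cdna_pos <= 49) rules <- c(rules, "penultimate_last50")
  }
  # (3) PTC < 150 nt away from the start codon
  if (ptc_cdna_pos - cds_start < 150) rules <- c(rules, "start_proximal_lt150")
  # (4) PTC in a long exon (> 400 nt)
  if (exon_lengths[exon_idx] > 400) rules <- c(rules, "long_exon_gt400")
  list(escaping = length(rules) > 0, rules = rules)
}

random_cdna <- function(total, cds_start, n_codons) {
  utr5 <- if (cds_start > 1) {
    paste(sample(c("A", "C", "G", "T"), cds_start - 1, replace = TRUE),
          collapse = "")
  } else ""
  coding <- c("ATG", sample(NON_STOP_CODONS, n_codons - 2, replace = TRUE),
              sample(STOP_CODONS, 1))
  tail_len <- total - (cds_start - 1) - 3 * n_codons
  utr3 <- if (tail_len > 0) {
    paste(sample(c("A", "C", "G", "T"), tail_len, replace = TRUE),
          collapse = "")
  } else ""
  paste0(utr5, paste(coding, collapse = ""), utr3)
}

# single-nucleotide substitution turning the codon at `p` into a stop, if any
stop_substitution <- function(cdna, p) {
  codon <- substr(cdna, p, p + 2L)
  for (off in 0:2) for (nt in c("A", "C", "G", "T")) {
    if (substr(codon, off + 1L, off + 1L) == nt) next
    cand <- codon
    substr(cand, off + 1L, off + 1L) <- nt
    if (cand %in% STOP_CODONS) {
      return(list(pos = p + off, ref = substr(codon, off + 1L, off + 1L),
                  alt = nt))
    }
  }
  NULL
}

#' Simulate gene models with truncating variants and ground truth
#'
#' Random multi-exon transcripts (2-10 exons of 50-600 nt) receive nonsense
#' and frameshift variants; the shipped truth table records each variant's
#' PTC and its NMD verdict as computed by the literal rule reference
#' ([nmd_rules_reference()]). Five designed transcripts guaranteeing coverage
#' of every escape rule plus an NMD-causing case are always appended. A few
#' decoy variants violating the pathogenicity filters are included.
#'
#' @param n_genes Number of random genes.
#' @param seed Integer seed.
#' @return List with `models` (gene-model tibble including `cdna`),
#'   `features` (exon-level table for [write_gene_models_gtf()]), `cdna`
#'   (tibble for FASTA export), `variants`, and `truth`.
#' @export
simulate_gene_models_variants <- function(n_genes = 20, seed = 1) {
  withr::with_seed(derive_seed(seed, 25L), {
    genes <- vector("list", n_genes)
    cursor <- 1000L
    for (g in seq_len(n_genes)) {
      n_ex <- sample(2:10, 1)
      exl <- sample(50:600, n_ex, replace = TRUE)
      strand <- sample(c("+", "-"), 1)
      total <- sum(exl)
      cds_start <- sample.int(min(300L, total - 62L), 1)
      max_codons <- (total - cds_start - 1L) %/% 3L
      n_codons <- sample(18:max(19, max_codons - 2L), 1)
      n_codons <- min(n_codons, max_codons)
      genes[[g]] <- list(id = sprintf("G%03d", g), n_ex = n_ex, exl = exl,
                         strand = strand, cds_start = cds_start,
                         cdna = random_cdna(total, cds_start, n_codons),
                         n_codons = n_codons, origin = cursor)
      cursor <- cursor + total + n_ex * 400L + 2000L
    }
    # designed transcripts: exon layout [200, 350, 300] or [200, 450, 300],
    # PTCs placed to fire each rule exactly once and one causing case
    designed <- list(
      list(id = "D_last",   exl = c(200L, 350L, 300L), ptc_codon_pos = 700L),
      list(id = "D_pen50",  exl = c(200L, 350L, 300L), ptc_codon_pos = 520L),
      list(id = "D_start",  exl = c(200L, 350L, 300L), ptc_codon_pos = 119L),
      list(id = "D_longex", exl = c(200L, 450L, 300L), ptc_codon_pos = 400L),
      list(id = "D_cause",  exl = c(200L, 350L, 300L), ptc_codon_pos = 299L))
    for (d in designed) {
      total <- sum(d$exl)
      cds_start <- 101L
      # align the requested PTC to the reading frame
      ptc <- cds_start + 3L * ((d$ptc_codon_pos - cds_start) %/% 3L)
      n_codons <- (total - cds_start - 1L) %/% 3L - 2L
      cdna <- random_cdna(total, cds_start, n_codons)
      substr(cdna, ptc, ptc + 2L) <- "CAA" # guarantees a C>T nonsense allele
      genes[[length(genes) + 1L]] <- list(
        id = d$id, n_ex = length(d$exl), exl = d$exl, strand = "+",
        cds_start = cds_start, cdna = cdna,
        n_codons = n_codons, origin = cursor, force_ptc = ptc)
      cursor <- cursor + total + 3000L
    }
    feat <- list()
    models <- list()
    cdna_tbl <- list()
    variants <- list()
    truth <- list()
    vid <- 0L
    for (gi in seq_along(genes)) {
      gn <- genes[[gi]]
      total <- sum(gn$exl)
      # genomic exon layout: introns of 100-800 nt between exons
      introns <- if (gn$n_ex > 1) sample(100:800, gn$n_ex - 1, replace = TRUE)
                 else integer(0)
      widths <- gn$exl
      if (gn$strand == "-") widths <- rev(widths) # genomic order
      starts <- integer(gn$n_ex)
      s <- gn$origin
      for (i in seq_len(gn$n_ex)) {
        starts[i] <- s
        s <- s + widths[i] + (if (i < gn$n_ex) introns[i] else 0L)
      }
      ends <- starts + widths - 1L
      tx <- paste0("T_", gn$id)
      # start-codon genomic coordinates from the cDNA cds_start
      exon_order <- if (gn$strand == "+") seq_len(gn$n_ex)
                    else rev(seq_len(gn$n_ex))
      cum <- cumsum(gn$exl)
      ex_of_cds <- findInterval(gn$cds_start - 1, c(0, cum[-gn$n_ex]))
      off <- gn$cds_start - (if (ex_of_cds > 1) cum[ex_of_cds - 1L] else 0L)
      gex <- exon_order[ex_of_cds]
      g_cds <- if (gn$strand == "+") starts[gex] + off - 1L
               else ends[gex] - off + 1L
      feat[[length(feat) + 1L]] <- tibble::tibble(
        seqname = "chr1", source = "psdosage",
        type = c(rep("exon", gn$n_ex), "start_codon"),
        start = c(starts, if (gn$strand == "+") g_cds else g_cds - 2L),
        end = c(ends, if (gn$strand == "+") g_cds + 2L else g_cds),
        strand = gn$strand, gene_id = gn$id, transcript_id = tx)
      models[[length(models) + 1L]] <- tibble::tibble(
        gene_id = gn$id, transcript_id = tx, strand = gn$strand,
        n_exons = gn$n_ex, exon_lengths = list(gn$exl),
        cds_start = gn$cds_start, cdna = gn$cdna)
      cdna_tbl[[length(cdna_tbl) + 1L]] <- tibble::tibble(id = tx,
                                                          sequence = gn$cdna)
      # nonsense variants
      codon_starts <- gn$cds_start + 3L * seq(1L, gn$n_codons - 2L)
      want <- if (!is.null(gn$force_ptc)) gn$force_ptc
              else sample(codon_starts, min(3, length(codon_starts)))
      for (p in want) {
        sub <- stop_substitution(gn$cdna, p)
        if (is.null(sub)) next
        vid <- vid + 1L
        variants[[length(variants) + 1L]] <- tibble::tibble(
          variant_id = sprintf("V%04d", vid), gene_id = gn$id,
          transcript_id = tx, cdna_pos = sub$pos, ref = sub$ref,
          alt = sub$alt, consequence = "stop_gained",
          clinical_significance = "Pathogenic",
          review_stars = sample(1:3, 1), has_conflicts = FALSE)
        ref_v <- nmd_rules_reference(p, gn$exl, gn$cds_start)
        truth[[length(truth) + 1L]] <- tibble::tibble(
          variant_id = sprintf("V%04d", vid), ptc_cdna_pos = p,
          escaping = ref_v$escaping,
          rules = paste(ref_v$rules, collapse = ","))
      }
      # one frameshift (1-nt deletion inside the coding region)
      if (is.null(gn$force_ptc) && gn$n_codons > 12) {
        del_at <- gn$cds_start + 3L * sample(3:8, 1)
        vid <- vid + 1L
        ref <- substr(gn$cdna, del_at, del_at + 1L)
        variants[[length(variants) + 1L]] <- tibble::tibble(
          variant_id = sprintf("V%04d", vid), gene_id = gn$id,
          transcript_id = tx, cdna_pos = del_at, ref = ref,
          alt = substr(ref, 1L, 1L), consequence = "frameshift_variant",
          clinical_significance = "Likely pathogenic",
          review_stars = sample(1:2, 1), has_conflicts = FALSE)
        mutated <- paste0(substr(gn$cdna, 1L, del_at),
                          substr(gn$cdna, del_at + 2L, nchar(gn$cdna)))
        # independent stop scan on the mutated transcript
        fs_ptc <- NA_integer_
        p <- gn$cds_start
        while (p + 2L <= nchar(mutated)) {
          if (substr(mutated, p, p + 2L) %in% STOP_CODONS) {
            fs_ptc <- p
            break
          }
          p <- p + 3L
        }
        if (is.na(fs_ptc)) {
          truth[[length(truth) + 1L]] <- tibble::tibble(
            variant_id = sprintf("V%04d", vid), ptc_cdna_pos = NA_integer_,
            escaping = NA, rules = "no_stop")
        } else {
          ref_v <- nmd_rules_reference(fs_ptc, gn$exl, gn$cds_start)
          truth[[length(truth) + 1L]] <- tibble::tibble(
            variant_id = sprintf("V%04d", vid), ptc_cdna_pos = fs_ptc,
            escaping = ref_v$escaping,
            rules = paste(ref_v$rules, collapse = ","))
        }
      }
    }
    # decoys that every pathogenicity filter must remove
    first_tx <- models[[1]]
    decoys <- tibble::tibble(
      variant_id = sprintf("DEC%d", 1:3),
      gene_id = first_tx$gene_id, transcript_id = first_tx$transcript_id,
      cdna_pos = c(10L, 11L, 12L), ref = "A", alt = "T",
      consequence = "stop_gained",
      clinical_significance = c("Benign", "Pathogenic", "Pathogenic"),
      review_stars = c(2L, 0L, 2L),
      has_conflicts = c(FALSE, FALSE, TRUE))
    list(models = dplyr::bind_rows(models),
         features = dplyr::bind_rows(feat),
         cdna = dplyr::bind_rows(cdna_tbl),
         variants = dplyr::bind_rows(c(variants, list(decoys))),
         truth = dplyr::bind_rows(truth))
  })
}

# --- dosage-score tables -----------------------------------------------------

#' Simulate a dosage-score table with a planted class shift
#'
#' Latent per-gene, per-feature scores are standard normal; phase-separating
#' genes are shifted by `+d` standard deviations on each informative
#' probability-like feature and by `-d` on LOEUF (lower LOEUF means more
#' constrained) before mapping onto the reported scales (logistic for
#' pLI/pHaplo/pTriplo, exponential for LOEUF). Because the maps are strictly
#' monotone, rank statistics such as AUC are unchanged by them, and a single
#' informative feature with shift `d` has expected AUC `pnorm(d / sqrt(2))`.
#'
#' @param n_ps,n_nonps Genes per class.
#' @param d Standardized mean shift (>= 0).
#' @param informative Character subset of
#'   `c("pli", "loeuf", "phaplo", "ptriplo")` that carries the shift.
#' @param seed Integer seed.
#' @param missing_rate Per-cell missingness probability.
#' @param train_frac Fraction of each class labelled `split = "train"`.
#' @return List with `scores` (schema `"dosage"`) and `labels` (`id`,
#'   `class`, `split`).
#' @export
simulate_dosage_table <- function(n_ps, n_nonps, d = 2,
                                  informative = c("pli"), seed = 1,
                                  missing_rate = 0, train_frac = 0.65) {
  if (d < 0) abort_ps("d must be >= 0", "psdosage_validation_error")
  withr::with_seed(derive_seed(seed, 26L), {
    n <- n_ps + n_nonps
    is_ps <- c(rep(TRUE, n_ps), rep(FALSE, n_nonps))
    ids <- c(sprintf("PSG%04d", seq_len(n_ps)),
             sprintf("NPG%04d", seq_len(n_nonps)))
    latent <- function(feature) {
      z <- stats::rnorm(n)
      if (feature %in% informative) {
        z[is_ps] <- z[is_ps] + if (feature == "loeuf") -d else d
      }
      z
    }
    scores <- tibble::tibble(
      gene_id = ids,
      pli = stats::plogis(latent("pli")),
      loeuf = exp(0.45 * latent("loeuf") - 0.3),
      phaplo = stats::plogis(latent("phaplo")),
      ptriplo = stats::plogis(latent("ptriplo")))
    if (missing_rate > 0) {
      for (f in DOSPS_FEATURES) {
        hole <- stats::runif(n) < missing_rate
        scores[[f]][hole] <- NA_real_
      }
    }
    ps_class <- rep(c("self-assembling", "partner-dependent"),
                    length.out = n_ps)
    split_of <- function(k) {
      rep(c("train", "test"), c(round(train_frac * k),
                                k - round(train_frac * k)))
    }
    labels <- tibble::tibble(
      id = ids,
      class = c(ps_class, rep("non-PS", n_nonps)),
      split = c(split_of(n_ps), split_of(n_nonps)))
    list(scores = scores, labels = labels)
  })
}

#' Simulate a per-residue embedding provider
#'
#' Returns a closure usable as the `embedder` argument of
#' [region_features()]: rows are i.i.d. noise plus a class-dependent mean
#' offset, with no biological structure beyond that.
#'
#' @param proteins Tibble with `id`, `sequence`.
#' @param ps_ids Ids receiving the mean offset.
#' @param dim Embedding dimension (the full-scale convention is 3705;
#'   smaller values keep tests fast).
#' @param offset Mean shift applied to PS-like proteins.
#' @param seed Integer seed.
#' @return `function(protein_id)` yielding an L x `dim` matrix,
#'   deterministic per protein.
#' @export
simulate_embedder <- function(proteins, ps_ids = character(0), dim = 16,
                              offset = 0.5, seed = 1) {
  lens <- stats::setNames(nchar(proteins$sequence), proteins$id)
  function(protein_id) {
    L <- lens[[protein_id]]
    withr::with_seed(
      derive_seed(seed, 27L + sum(utf8ToInt(protein_id))), {
        m <- matrix(stats::rnorm(L * dim), nrow = L)
        if (protein_id %in% ps_ids) m <- m + offset
        m
      })
  }
}
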