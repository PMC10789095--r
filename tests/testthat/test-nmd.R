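# Pathogenic-variant filtering, PTC derivation, NMD-escape rules.

toy_variants <- function() {
  tibble::tibble(
    gene_id = "g", transcript_id = "t", cdna_pos = 1:6, ref = "A", alt = "T",
    consequence = "stop_gained",
    clinical_significance = c("Pathogenic", "Likely pathogenic",
                              "Pathogenic/Likely pathogenic", "Benign",
                              "Pathogenic", "Pathogenic"),
    review_stars = c(2L, 1L, 3L, 2L, 0L, 2L),
    has_conflicts = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
}

test_that("pathogenicity filter applies all three rules and is idempotent", {
  v <- toy_variants()
  kept <- filter_pathogenic(v)
  expect_equal(kept$cdna_pos, 1:3) # one row violates each rule
  expect_identical(filter_pathogenic(kept), kept)
  # zero stars is dropped even when pathogenic
  expect_equal(nrow(filter_pathogenic(v[5, , drop = FALSE])), 0)
  # unknown significance terms never pass silently
  v$clinical_significance[1] <- "mystery term"
  expect_warning(out <- filter_pathogenic(v), "mystery term")
  expect_equal(out$cdna_pos, 2:3)
})

test_that("CNV mode additionally requires copy number loss", {
  v <- tibble::tibble(
    gene_id = c("a", "b"), transcript_id = NA, cdna_pos = NA,
    ref = "-", alt = "+",
    consequence = c("copy number loss", "copy number gain"),
    clinical_significance = "Pathogenic", review_stars = 1L,
    has_conflicts = FALSE)
  expect_equal(filter_pathogenic(v, "cnv-loss")$gene_id, "a")
})

test_that("consequence terms map onto PTV classes", {
  expect_identical(
    classify_ptv(c("stop_gained", "frameshift_variant",
                   "splice_region_variant", "missense_variant")),
    c("nonsense", "frameshift", "splice", "not-ptv"))
})

test_that("nonsense PTC is the first nucleotide of the affected codon", {
  expect_equal(ptc_from_nonsense(121, 101), 119)
  expect_equal(ptc_from_nonsense(4, 1), 4)
  expect_equal(ptc_from_nonsense(103, 101), 101)
  expect_error(ptc_from_nonsense(50, 101), class = "psdosage_validation_error")
  # with sequence: the substituted codon must actually be a stop
  cdna <- paste0(strrep("G", 100), "ATGCAAGAATTTTGA", strrep("G", 20))
  expect_equal(ptc_from_nonsense(104, 101, cdna, ref = "C", alt = "T"), 104)
  expect_error(ptc_from_nonsense(104, 101, cdna, ref = "C", alt = "G"),
               class = "psdosage_validation_error")
})

test_that("frameshift PTC comes from translation in the shifted frame", {
  # ATG AAA TAA: deleting nucleotide 4 shifts to ATG AAT AA. -> scan onward
  cdna <- paste0("ATGAAATAACCC", "TTTGGG")
  fs <- ptc_from_frameshift(4, "AA", "A", 1, cdna)
  # mutated: ATG AAT AAC CCT TTG GG -> no stop until none; oracle check below
  mutated <- paste0(substr(cdna, 1, 3), substr(cdna, 5, nchar(cdna)))
  stops <- which(vapply(seq(1, nchar(mutated) - 2, by = 3), function(p)
    substr(mutated, p, p + 2) %in% c("TAA", "TAG", "TGA"), TRUE))
  expect_identical(fs$status, if (length(stops) > 0) "ok" else "no_stop")

  # insertion creating an immediate stop at the next codon
  cdna2 <- "ATGTTTAACCCGGG"
  # insert A after pos 3: ATG A TTT AAC ... -> codon 2 of new frame is TTT? no:
  # new seq ATG ATT TAA ... -> stop at position 7
  fs2 <- ptc_from_frameshift(3, "G", "GA", 1, cdna2)
  expect_identical(fs2$status, "ok")
  expect_equal(fs2$ptc_cdna_pos, 7)
  expect_identical(fs2$coords, "mutated")

  # stop-free tail in every frame
  cdna3 <- paste0("ATG", strrep("CAC", 20))
  fs3 <- ptc_from_frameshift(4, "CA", "C", 1, cdna3)
  expect_identical(fs3$status, "no_stop")

  # in-frame indel is rejected
  expect_error(ptc_from_frameshift(4, "AAAT", "A", 1, cdna),
               class = "psdosage_validation_error")
})

test_that("the four escape rules follow the published boundaries", {
  exl <- c(200L, 350L, 300L)
  # no rule fires: exon 2, above the last-50 window, far from start, short exon
  v <- classify_nmd(300, exl, cds_start = 101)
  expect_false(v$escaping)
  expect_identical(v$rules, "")
  # last exon
  v1 <- classify_nmd(800, exl, cds_start = 101)
  expect_true(v1$last_exon)
  expect_identical(v1$rules, "last_exon")
  # last 50 nt of the penultimate exon: positions 501..550
  expect_true(classify_nmd(501, exl, 101)$penultimate_last50)
  expect_true(classify_nmd(550, exl, 101)$penultimate_last50)
  expect_false(classify_nmd(500, exl, 101)$penultimate_last50)
  # start proximity is strict at 150 nt
  expect_true(classify_nmd(101 + 149, exl, 101)$start_proximal_lt150)
  expect_false(classify_nmd(101 + 150, exl, 101)$start_proximal_lt150)
  v3 <- classify_nmd(120, exl, 101)
  expect_identical(v3$rules, "start_proximal_lt150")
  # long-exon rule is strict at 400 nt
  expect_false(classify_nmd(300, c(200L, 400L, 300L), 101)$long_exon_gt400)
  expect_true(classify_nmd(300, c(200L, 401L, 300L), 101)$long_exon_gt400)
  # single-exon transcripts always escape via rule 1
  expect_true(classify_nmd(100, 600L, 1)$last_exon)
  # cds_start needed only when no other rule decides
  expect_true(classify_nmd(800, exl, NA)$escaping)
  expect_error(classify_nmd(300, exl, NA),
               class = "psdosage_validation_error")
  expect_error(classify_nmd(849, exl, 101),
               class = "psdosage_validation_error")
})

test_that("classify_nmd agrees with the literal rule transcription", {
  sim <- simulate_gene_models_variants(40, seed = 9)
  for (i in seq_len(nrow(sim$models))) {
    exl <- sim$models$exon_lengths[[i]]
    cds <- sim$models$cds_start[i]
    total <- sum(exl)
    ptcs <- seq(cds, total - 2L, by = 3L)
    got <- classify_nmd(ptcs, exl, cds)
    want <- lapply(ptcs, nmd_rules_reference, exon_lengths = exl,
                   cds_start = cds)
    expect_identical(got$escaping, vapply(want, `[[`, TRUE, "escaping"))
    expect_identical(got$rules,
                     vapply(want, function(w) paste(w$rules, collapse = ","),
                            ""))
  }
})

test_that("the variant pipeline matches the shipped truth table", {
  sim <- simulate_gene_models_variants(15, seed = 2)
  filt <- filter_pathogenic(sim$variants)
  res <- nmd_classify_variants(filt, sim$models)
  cmp <- dplyr::inner_join(
    dplyr::mutate(res, variant_id = filt$variant_id),
    sim$truth, by = "variant_id", suffix = c("", ".truth"))
  expect_gt(nrow(cmp), 20)
  ok <- cmp$status == "ok"
  expect_identical(cmp$ptc_cdna_pos[ok], cmp$ptc_cdna_pos.truth[ok])
  expect_identical(cmp$escaping[ok], cmp$escaping.truth[ok])
  expect_identical(cmp$rules[ok], cmp$rules.truth[ok])
  expect_identical(cmp$status[cmp$rules.truth == "no_stop"],
                   rep("no_stop", sum(cmp$rules.truth == "no_stop")))
  # splice variants carry no verdict
  splice <- filt[1, ]
  splice$consequence <- "splice_region_variant"
  out <- nmd_classify_variants(splice, sim$models)
  expect_identical(out$status, "NMD-undetermined")
  expect_true(is.na(out$escaping))
  # truncation bookkeeping: lost fraction in (0, 1]
  tf <- cmp$trunc_fraction[ok & !is.na(cmp$trunc_fraction)]
  expect_true(all(tf > 0 & tf <= 1))
})
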