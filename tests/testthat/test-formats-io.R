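# Readers/writers: FASTA, schema TSV, GTF gene models, model files.

test_that("protein FASTA parsing folds case, joins wraps, validates", {
  f <- tmp_write_lines(c(">p1 some description", "mk", "vl"))
  res <- read_protein_fasta(f)
  expect_equal(res$id, "p1")
  expect_equal(res$sequence, "MKVL")

  single <- tmp_write_lines(c(">p1", "MKV"))
  expect_equal(read_protein_fasta(single)$sequence, "MKV")

  bad <- tmp_write_lines(c(">p1", "MKB"))
  expect_error(read_protein_fasta(bad), "B",
               class = "psdosage_validation_error")
  dup <- tmp_write_lines(c(">p1", "MK", ">p1", "VL"))
  expect_error(read_protein_fasta(dup), class = "psdosage_validation_error")
  empty <- tmp_write_lines(character(0))
  expect_error(read_protein_fasta(empty), class = "psdosage_parse_error")
})

test_that("FASTA roundtrip preserves records", {
  withr::with_seed(5, {
    prot <- tibble::tibble(id = c("a", "b", "c"),
                           sequence = vapply(c(10, 75, 130), random_aa_seq, ""))
    f <- withr::local_tempfile(fileext = ".fasta")
    write_protein_fasta(prot, f)
    expect_equal(read_protein_fasta(f), prot)
  })
})

test_that("schema TSV reading types columns and flags missing ones", {
  f <- tmp_write_lines(c(
    "gene_id\tpli\tloeuf\tphaplo\tptriplo\textra",
    "g1\t0.9\t0.2\t0.8\t0.7\thello",
    "g2\tNA\t0.5\t0.1\t0.2\tworld"))
  tab <- read_ps_tsv(f, "dosage")
  expect_equal(nrow(tab), 2)
  expect_type(tab$pli, "double")
  expect_true(is.na(tab$pli[2])) # missing marker, row retained
  expect_identical(tab$extra, c("hello", "world")) # extras preserved

  bad <- tmp_write_lines(c("gene_id\tpli\tloeuf\tphaplo", "g1\t1\t1\t1"))
  err <- expect_error(read_ps_tsv(bad, "dosage"),
                      class = "psdosage_schema_error")
  expect_match(conditionMessage(err), "ptriplo")
  expect_error(ps_schema("nope"), class = "psdosage_validation_error")
})

test_that("GTF gene models map genomic to cDNA coordinates by strand", {
  # plus strand: exons (101-200), (301-400); start codon at genomic 151
  lines <- c(
    'chr1\tt\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tt\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tt\tCDS\t151\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    # minus strand, same genomic exons, CDS ending at genomic 350
    'chr1\tt\texon\t101\t200\t.\t-\t.\tgene_id "g2"; transcript_id "t2";',
    'chr1\tt\texon\t301\t400\t.\t-\t.\tgene_id "g2"; transcript_id "t2";',
    'chr1\tt\tCDS\t301\t350\t.\t-\t.\tgene_id "g2"; transcript_id "t2";',
    # exon-only transcript
    'chr1\tt\texon\t500\t579\t.\t+\t.\tgene_id "g3"; transcript_id "t3";')
  f <- tmp_write_lines(lines)
  m <- read_gene_models(f)
  t1 <- m[m$transcript_id == "t1", ]
  expect_equal(t1$exon_lengths[[1]], c(100L, 100L))
  expect_equal(t1$cds_start, 51L)
  # minus strand: cDNA starts at genomic 400; genomic 350 is cDNA 51
  t2 <- m[m$transcript_id == "t2", ]
  expect_equal(t2$exon_lengths[[1]], c(100L, 100L))
  expect_equal(t2$cds_start, 51L)
  t3 <- m[m$transcript_id == "t3", ]
  expect_true(is.na(t3$cds_start))
})

test_that("GTF validation rejects overlapping exons", {
  f <- tmp_write_lines(c(
    'chr1\tt\texon\t1\t100\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    'chr1\tt\texon\t50\t150\t.\t+\t.\tgene_id "g"; transcript_id "t";'))
  expect_error(read_gene_models(f), class = "psdosage_validation_error")
})

test_that("simulated annotations survive a GTF + cDNA roundtrip", {
  sim <- simulate_gene_models_variants(8, seed = 3)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_gene_models_gtf(sim$features, gtf)
  write_cdna_fasta(sim$cdna, fa)
  m <- read_gene_models(gtf, fa)
  expect_setequal(m$transcript_id, sim$models$transcript_id)
  for (i in seq_len(nrow(sim$models))) {
    j <- match(sim$models$transcript_id[i], m$transcript_id)
    expect_identical(m$exon_lengths[[j]], sim$models$exon_lengths[[i]])
    expect_identical(m$cds_start[j], sim$models$cds_start[i])
    expect_identical(m$cdna[j], sim$models$cdna[i])
  }
})

test_that("model files roundtrip exactly and refuse tampered content", {
  withr::with_seed(8, {
    train <- simulate_dosage_table(40, 120, d = 2, informative = "pli",
                                   seed = 1)
    model <- fit_dosps(train$scores, train$labels, grid = c(1), seeds = 1L,
                       neg_sample = 60, seed = 1)
    f <- withr::local_tempfile(fileext = ".json")
    write_ps_model(model, f)
    back <- read_ps_model(f)
    p1 <- predict_dosps(model, train$scores)
    p2 <- predict_dosps(back, train$scores)
    expect_identical(p1$dosps, p2$dosps)

    # permuted top-level feature list is rejected as incompatible
    payload <- jsonlite::read_json(f, simplifyVector = TRUE)
    payload$feature_names <- rev(payload$feature_names)
    jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA)
    expect_error(read_ps_model(f), class = "psdosage_incompatible_model")

    # truncated file never yields a partial model
    writeLines(substr(paste(readLines(f, warn = FALSE), collapse = ""), 1, 40),
               f)
    expect_error(read_ps_model(f), class = "psdosage_parse_error")
  })
})

test_that("tree-ensemble model files reproduce predictions bitwise", {
  withr::with_seed(14, {
    n <- 60
    feats <- tibble::tibble(
      hydropathy = runif(n), kappa = runif(n), kappa_defined = 1,
      ncpr = runif(n, -0.5, 0.5), idr_prop = runif(n), lcd_prop = runif(n))
    labels <- as.integer(feats$idr_prop + 0.3 * feats$lcd_prop +
                           rnorm(n, 0, 0.05) > 0.6)
    if (min(table(labels)) < 10) labels[1:12] <- rep(0:1, 6)
    model <- train_truncps(feats, labels, nrounds = 20, seed = 1)
    f <- withr::local_tempfile(fileext = ".json")
    write_ps_model(model, f)
    back <- read_ps_model(f)
    expect_identical(predict(model, feats), predict(back, feats))
    expect_identical(back$feature_names, model$feature_names)
  })
})
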