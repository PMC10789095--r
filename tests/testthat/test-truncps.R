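# TruncPS: negative sampling, feature assembly, training, CV, truncation
# scoring.

test_that("negative sampling honours the 2:1 ratio and length distribution", {
  withr::with_seed(30, {
    prots <- tibble::tibble(id = sprintf("p%02d", 1:30),
                            sequence = vapply(sample(200:600, 30, TRUE),
                                              random_aa_seq, ""))
    pos_len <- sample(25:180, 93, replace = TRUE)
    neg <- sample_negative_regions(prots, pos_len, ratio = 2, seed = 7)
    expect_equal(nrow(neg), 186)
    expect_true(all(neg$end - neg$start + 1 %in% pos_len))
    expect_true(all(neg$source == "nonps-sampled"))
    lens <- nchar(prots$sequence)[match(neg$protein_id, prots$id)]
    expect_true(all(neg$end <= lens))
    expect_identical(neg, sample_negative_regions(prots, pos_len, 2, seed = 7))
    # sampled lengths are distributed like the positive lengths
    drawn <- neg$end - neg$start + 1
    ks <- suppressWarnings(stats::ks.test(drawn, pos_len))
    expect_gt(ks$p.value, 0.01)
  })
})

test_that("single eligible placement is found deterministically", {
  prots <- tibble::tibble(id = "only", sequence = random_aa_seq(10))
  reg <- sample_negative_regions(prots, 10L, ratio = 1, seed = 1)
  expect_equal(reg$start, 1L)
  expect_equal(reg$end, 10L)
  expect_error(sample_negative_regions(prots, 50L, ratio = 1, seed = 1),
               class = "psdosage_validation_error")
})

test_that("region features are computed on the exact substring", {
  prot <- tibble::tibble(id = "p", sequence = paste0(strrep("I", 10),
                                                     strrep("E", 10)))
  reg <- tibble::tibble(protein_id = "p", start = c(1L, 11L), end = c(10L, 20L))
  f <- region_features(reg, prot)
  expect_equal(f$hydropathy, c(1, (-3.5 + 4.5) / 9), tolerance = 1e-12)
  expect_equal(f$ncpr, c(0, -1))
  expect_error(
    region_features(tibble::tibble(protein_id = "p", start = 5L, end = 25L),
                    prot),
    class = "psdosage_validation_error")
})

test_that("embedding pooling takes column means over region rows", {
  prot <- tibble::tibble(id = "p", sequence = random_aa_seq(30))
  const_embedder <- function(id) matrix(rep(c(1, 2, 3), each = 30), nrow = 30)
  f <- region_features(tibble::tibble(protein_id = "p", start = 1L, end = 30L),
                       prot, embedder = const_embedder)
  expect_equal(unlist(f[, c("emb_1", "emb_2", "emb_3")], use.names = FALSE),
               c(1, 2, 3))
  short_embedder <- function(id) matrix(0, nrow = 10, ncol = 3)
  expect_error(
    region_features(tibble::tibble(protein_id = "p", start = 1L, end = 5L),
                    prot, embedder = short_embedder),
    class = "psdosage_validation_error")
  # without an embedder only the scalar features appear
  f2 <- region_features(tibble::tibble(protein_id = "p", start = 1L,
                                       end = 30L), prot)
  expect_false(any(grepl("^emb_", names(f2))))
})

synthetic_features <- function(n_per_class, sep = 3, seed = 99) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    labels <- rep(c(1L, 0L), each = n_per_class)
    tibble::tibble(
      hydropathy = rnorm(n, ifelse(labels == 1, 0.3, 0.6), 0.35 / sep),
      kappa = runif(n), kappa_defined = 1,
      ncpr = rnorm(n, 0, 0.1),
      idr_prop = rnorm(n, ifelse(labels == 1, 0.8, 0.2), 0.6 / sep),
      lcd_prop = runif(n), labels = labels)
  })
}

test_that("training separates separable data and is deterministic", {
  df <- synthetic_features(100, sep = 6)
  m <- train_truncps(df, df$labels, nrounds = 40, seed = 1)
  expect_equal(rank_auc(predict(m, df), df$labels), 1)
  m2 <- train_truncps(df, df$labels, nrounds = 40, seed = 1)
  expect_identical(predict(m, df), predict(m2, df))
  m3 <- train_truncps(df, df$labels, nrounds = 40, seed = 2)
  expect_false(identical(predict(m, df), predict(m3, df)))
  expect_error(train_truncps(df, rep(1, nrow(df))),
               class = "psdosage_validation_error")
  expect_error(train_truncps(df[1:15, ], c(rep(1, 8), rep(0, 7))),
               class = "psdosage_validation_error")
})

test_that("cross-validation is stratified, deterministic, honest under nulls", {
  df <- synthetic_features(50, sep = 4)
  cv <- crossval_auc(df, df$labels, k = 5, seed = 3, nrounds = 40)
  expect_equal(nrow(cv$per_fold), 5)
  expect_equal(cv$mean_auc, mean(cv$per_fold$auc))
  expect_identical(cv, crossval_auc(df, df$labels, k = 5, seed = 3,
                                    nrounds = 40))
  expect_gt(cv$mean_auc, 0.95)
  # label permutation: held-out AUC collapses to chance
  withr::with_seed(4, perm <- sample(df$labels))
  cvp <- crossval_auc(df, perm, k = 5, seed = 3, nrounds = 40)
  expect_lt(abs(cvp$mean_auc - 0.5), 0.1)
  # a leaked perfect scorer is recovered as AUC 1 on every fold
  leak <- dplyr::mutate(df, idr_prop = labels, hydropathy = 0, kappa = 0,
                        lcd_prop = 0, ncpr = 0)
  cvl <- crossval_auc(leak, leak$labels, k = 5, seed = 1, nrounds = 20)
  expect_true(all(cvl$per_fold$auc == 1))
})

test_that("truncation calls score the lost suffix with correct bookkeeping", {
  df <- synthetic_features(50, sep = 4)
  m <- train_truncps(df, df$labels, nrounds = 30, seed = 1)
  prot <- tibble::tibble(id = "p", sequence = random_aa_seq(265))
  call <- score_truncation(prot, 142, m)
  expect_equal(call$start, 142L)
  expect_equal(call$end, 265L)
  expect_equal(call$trunc_fraction, 124 / 265, tolerance = 1e-12)
  expect_gte(call$truncps_score, 0)
  expect_lte(call$truncps_score, 1)
  # boundary: losing only the final residue is a valid single-residue region
  last <- score_truncation(prot, 265, m)
  expect_equal(last$trunc_fraction, 1 / 265)
  expect_error(score_truncation(prot, 1, m),
               class = "psdosage_validation_error")
  expect_error(score_truncation(prot, 300, m),
               class = "psdosage_validation_error")
})
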