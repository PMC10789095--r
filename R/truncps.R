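# TruncPS: scoring the phase-separation potential of protein regions lost to
# truncating variants. Negative-region sampling, feature assembly, gradient
# boosted training (xgboost), cross-validation and truncation scoring.

#' Sample negative regions from non-phase-separating proteins
#'
#' Region lengths are drawn with replacement from the positive-region length
#' distribution and placed uniformly on a uniformly chosen protein long
#' enough to hold them, yielding `ratio` negatives per positive (default 2,
#' the curation convention).
#'
#' @param proteins Tibble with `id`, `sequence` (the non-PS protein set).
#' @param positive_lengths Integer vector of positive-region lengths.
#' @param ratio Negatives per positive.
#' @param seed Integer seed.
#' @param max_retries Bounded resampling attempts when a drawn length fits no
#'   protein.
#' @return Region tibble (`protein_id`, `start`, `end`, `label`, `source`).
#' @export
sample_negative_regions <- function(proteins, positive_lengths, ratio = 2,
                                    seed = 1, max_retries = 100) {
  if (ratio < 1) abort_ps("ratio must be >= 1", "psdosage_validation_error")
  plen <- nchar(proteins$sequence)
  n_target <- ratio * length(positive_lengths)
  withr::with_seed(derive_seed(seed, 3L), {
    rows <- vector("list", n_target)
    for (i in seq_len(n_target)) {
      len <- NA_integer_
      for (try in seq_len(max_retries)) {
        cand <- positive_lengths[sample.int(length(positive_lengths), 1)]
        if (any(plen >= cand)) {
          len <- cand
          break
        }
      }
      if (is.na(len)) {
        abort_ps("no protein can hold any drawn region length",
                 "psdosage_validation_error")
      }
      eligible <- which(plen >= len)
      p <- eligible[sample.int(length(eligible), 1)]
      start <- sample.int(plen[p] - len + 1L, 1)
      rows[[i]] <- tibble::tibble(
        protein_id = proteins$id[p], start = start,
        end = start + len - 1L, label = "negative",
        source = "nonps-sampled")
    }
    dplyr::bind_rows(rows)
  })
}

#' Assemble features for labelled regions
#'
#' Computes the five scalar composition features (plus the kappa-definedness
#' indicator) on each region's substring, and optionally mean-pools a
#' per-residue embedding over the region (column means of the provider's
#' L x E matrix restricted to the region rows).
#'
#' @param regions Region tibble with `protein_id`, `start`, `end` (1-based
#'   closed residue coordinates) and any label columns, which are preserved.
#' @param proteins Tibble with `id`, `sequence`.
#' @param embedder Optional function `f(protein_id)` returning the protein's
#'   L x E embedding matrix.
#' @return The region tibble with feature columns appended (`emb_1..emb_E`
#'   when an embedder is supplied).
#' @export
region_features <- function(regions, proteins, embedder = NULL) {
  seqs <- proteins$sequence[match(regions$protein_id, proteins$id)]
  if (anyNA(seqs)) {
    abort_ps(sprintf("no protein sequence for id(s): %s",
                     paste(unique(regions$protein_id[is.na(seqs)]),
                           collapse = ", ")),
             "psdosage_validation_error")
  }
  L <- nchar(seqs)
  if (any(regions$start < 1 | regions$end > L | regions$start > regions$end)) {
    abort_ps("region outside protein bounds", "psdosage_validation_error")
  }
  feats <- purrr::map2(seqs, seq_len(nrow(regions)), function(s, i) {
    sub <- substr(s, regions$start[i], regions$end[i])
    sequence_features(sub)
  })
  out <- dplyr::bind_cols(tibble::as_tibble(regions), dplyr::bind_rows(feats))
  if (!is.null(embedder)) {
    emb <- purrr::map(seq_len(nrow(out)), function(i) {
      m <- embedder(out$protein_id[i])
      if (nrow(m) != L[i]) {
        abort_ps(sprintf(
          "embedding for %s has %d rows but the protein has %d residues",
          out$protein_id[i], nrow(m), L[i]), "psdosage_validation_error")
      }
      colMeans(m[out$start[i]:out$end[i], , drop = FALSE])
    })
    emat <- do.call(rbind, emb)
    colnames(emat) <- paste0("emb_", seq_len(ncol(emat)))
    out <- dplyr::bind_cols(out, tibble::as_tibble(emat))
  }
  out
}

truncps_feature_cols <- function(data) {
  scalar <- c("hydropathy", "kappa", "kappa_defined", "ncpr", "idr_prop",
              "lcd_prop")
  c(scalar, grep("^emb_", names(data), value = TRUE))
}

#' Train the TruncPS gradient-boosted classifier
#'
#' Binary probabilistic classifier over region features using xgboost.
#' Training is deterministic under a fixed seed and hyperparameters
#' (single-threaded). The kappa `-1` sentinel enters the trees as the literal
#' value alongside the `kappa_defined` indicator.
#'
#' @param features Data frame containing the feature columns (any other
#'   columns are ignored).
#' @param labels Binary vector: 1 = phase-separating region.
#' @param nrounds Boosting rounds (default 150).
#' @param max_depth,eta,subsample Tree depth, learning rate, row subsampling.
#' @param min_child_weight,gamma Leaf-coarseness regularizers; the defaults
#'   keep leaves large relative to the few-hundred-region training sets this
#'   model is built for, which stabilizes scores for inputs between the two
#'   class clouds.
#' @param seed Integer seed.
#' @return A `truncps_model` object.
#' @export
train_truncps <- function(features, labels, nrounds = 150, max_depth = 3,
                          eta = 0.1, subsample = 0.8, min_child_weight = 8,
                          gamma = 1, seed = 1) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) {
    abort_ps("training labels are constant", "psdosage_validation_error")
  }
  if (min(table(labels)) < 10) {
    abort_ps("need at least 10 examples per class",
             "psdosage_validation_error")
  }
  cols <- truncps_feature_cols(features)
  x <- as.matrix(features[, cols])
  storage.mode(x) <- "double"
  params <- list(objective = "binary:logistic", max_depth = max_depth,
                 eta = eta, subsample = subsample,
                 min_child_weight = min_child_weight, gamma = gamma,
                 nthread = 1, seed = derive_seed(seed, 11L))
  bst <- withr::with_seed(derive_seed(seed, 11L), {
    xgboost::xgb.train(params = params,
                       data = xgboost::xgb.DMatrix(x, label = labels),
                       nrounds = nrounds, verbose = 0)
  })
  structure(list(
    feature_names = cols,
    booster = bst,
    booster_raw = xgboost::xgb.save.raw(bst),
    params = params[c("objective", "max_depth", "eta", "subsample",
                      "min_child_weight", "gamma")],
    nrounds = nrounds, seed = seed,
    metadata = list(n_pos = sum(labels == 1), n_neg = sum(labels == 0))
  ), class = "truncps_model")
}

#' @export
print.truncps_model <- function(x, ...) {
  cat(sprintf(
    "TruncPS xgboost model: %d features, %d rounds, depth %s, eta %s (seed %d)\n",
    length(x$feature_names), x$nrounds, x$params$max_depth, x$params$eta,
    x$seed))
  cat(sprintf("  trained on %d positive / %d negative regions\n",
              x$metadata$n_pos, x$metadata$n_neg))
  invisible(x)
}

#' Predict phase-separation probabilities for regions
#'
#' @param object A `truncps_model`.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.truncps_model <- function(object, newdata, ...) {
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss) > 0) {
    abort_ps(sprintf("newdata lacks feature column(s): %s",
                     paste(miss, collapse = ", ")),
             "psdosage_validation_error")
  }
  x <- as.matrix(newdata[, object$feature_names])
  storage.mode(x) <- "double"
  as.numeric(stats::predict(object$booster, xgboost::xgb.DMatrix(x)))
}

#' @export
glance.truncps_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$feature_names), nrounds = x$nrounds,
                 max_depth = x$params$max_depth, eta = x$params$eta,
                 subsample = x$params$subsample, seed = x$seed,
                 n_pos = x$metadata$n_pos, n_neg = x$metadata$n_neg)
}

#' Stratified cross-validated AUC for TruncPS
#'
#' @param features Feature table (as from [region_features()]).
#' @param labels Binary labels.
#' @param k Folds (default 5).
#' @param seed Integer seed (controls folds and per-fold training).
#' @param ... Passed to [train_truncps()].
#' @return A `truncps_cv` object: per-fold AUC tibble plus the mean.
#' @export
crossval_auc <- function(features, labels, k = 5, seed = 1, ...) {
  labels <- as.integer(as.logical(labels))
  folds <- kfold_splits(seq_along(labels), labels, k = k, seed = seed)
  aucs <- vapply(seq_len(k), function(f) {
    te <- folds$fold == f
    m <- train_truncps(features[!te, , drop = FALSE], labels[!te],
                       seed = seed, ...)
    rank_auc(predict(m, features[te, , drop = FALSE]), labels[te])
  }, numeric(1))
  structure(list(per_fold = tibble::tibble(fold = seq_len(k), auc = aucs),
                 mean_auc = mean(aucs), k = k, seed = seed),
            class = "truncps_cv")
}

#' @export
print.truncps_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV AUC: mean %.4f (folds: %s)\n", x$k, x$mean_auc,
              paste(sprintf("%.3f", x$per_fold$auc), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.truncps_cv <- function(x, ...) x$per_fold

#' @export
glance.truncps_cv <- function(x, ...) {
  tibble::tibble(mean_auc = x$mean_auc, k = x$k, seed = x$seed)
}

#' Score the region lost to a truncating variant
#'
#' The truncated region is the wild-type residues lost: from the first
#' residue affected by the premature stop to the C-terminus. The retained
#' N-terminal fragment is not scored.
#'
#' @param protein One-row tibble (or list) with `id` and `sequence`.
#' @param first_lost_residue 1-based index of the first lost residue; must be
#'   greater than 1 (a truncation losing the whole protein is degenerate) and
#'   at most the protein length.
#' @param model A `truncps_model`.
#' @param embedder Optional per-residue embedding provider.
#' @return One-row tibble: `protein_id`, `first_lost_residue`, `start`,
#'   `end`, `trunc_fraction`, `truncps_score`.
#' @export
score_truncation <- function(protein, first_lost_residue, model,
                             embedder = NULL) {
  L <- nchar(protein$sequence)
  if (first_lost_residue <= 1 || first_lost_residue > L) {
    abort_ps(sprintf(
      "first_lost_residue must be in (1, %d]: whole-protein loss is degenerate",
      L), "psdosage_validation_error")
  }
  region <- tibble::tibble(protein_id = protein$id,
                           start = as.integer(first_lost_residue),
                           end = as.integer(L))
  feats <- region_features(region,
                           tibble::tibble(id = protein$id,
                                          sequence = protein$sequence),
                           embedder = embedder)
  tibble::tibble(
    protein_id = protein$id,
    first_lost_residue = as.integer(first_lost_residue),
    start = as.integer(first_lost_residue), end = as.integer(L),
    trunc_fraction = (L - first_lost_residue + 1) / L,
    truncps_score = predict(model, feats))
}

#' Sweep truncation points across a protein
#'
#' Scores every truncation from near the C-terminus toward the N-terminus,
#' the in-silico analogue of comparing progressively longer truncating
#' variants of one protein.
#'
#' @inheritParams score_truncation
#' @param step Residues between successive truncation points.
#' @param min_lost Smallest lost-region length scored (default 21, the
#'   curation floor below which the classifier never saw training regions).
#' @return Tibble with one row per truncation point: `first_lost_residue`,
#'   `lost_length`, `trunc_fraction`, `truncps_score`.
#' @export
truncation_sweep <- function(protein, model, step = 4, min_lost = 21,
                             embedder = NULL) {
  L <- nchar(protein$sequence)
  cuts <- seq(L - min_lost + 1L, 2L, by = -step)
  res <- dplyr::bind_rows(lapply(cuts, function(k) {
    score_truncation(protein, k, model, embedder = embedder)
  }))
  tibble::tibble(
    first_lost_residue = res$first_lost_residue,
    lost_length = L - res$first_lost_residue + 1L,
    trunc_fraction = res$trunc_fraction,
    truncps_score = res$truncps_score)
}
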