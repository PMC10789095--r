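# Evaluation and normalization machinery: rank AUC, repeated negative
# subsampling, stratified folds, and rolling-median confounder removal.

#' Rank-based ROC AUC
#'
#' Computed exactly from mid-ranks: `AUC = P(score_pos > score_neg) +
#' 0.5 * P(tie)`, equivalent to the Mann-Whitney U statistic divided by
#' `n_pos * n_neg`.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (0/1 or logical) of the same length.
#' @return AUC in `[0, 1]`.
#' @examples
#' rank_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)) # 1
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) {
    abort_ps("scores and labels must have equal length",
             "psdosage_validation_error")
  }
  if (anyNA(scores) || anyNA(labels)) {
    abort_ps("rank_auc does not accept missing values",
             "psdosage_validation_error")
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    abort_ps("AUC requires both classes to be present",
             "psdosage_validation_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Repeated negative-subsampling AUC
#'
#' The evaluation protocol for imbalanced positive sets: each repeat draws
#' `ratio * n_pos` negatives without replacement from the negative pool,
#' computes the rank AUC on positives plus that sample, and the mean over
#' repeats is reported. Draws are independent across repeats and fully
#' determined by `seed`.
#'
#' @param scores Named numeric vector, or a data frame with `id` and `score`
#'   columns.
#' @param positives Character vector of positive ids.
#' @param negative_pool Character vector of candidate negative ids.
#' @param ratio Negatives drawn per positive (default 2).
#' @param repeats Number of repeats (default 50).
#' @param seed Integer seed.
#' @return A `ps_eval` object: list with `auc` (per-repeat vector),
#'   `mean_auc`, and the protocol metadata.
#' @export
repeated_sampling_auc <- function(scores, positives, negative_pool,
                                  ratio = 2, repeats = 50, seed = 1) {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores$score, scores$id)
  }
  missing_ids <- setdiff(c(positives, negative_pool), names(scores))
  if (length(missing_ids) > 0) {
    abort_ps(sprintf("no score for id(s): %s",
                     paste(utils::head(missing_ids, 5), collapse = ", ")),
             "psdosage_validation_error")
  }
  n_pos <- length(positives)
  n_draw <- ratio * n_pos
  if (length(negative_pool) < n_draw) {
    abort_ps(sprintf(
      "negative pool has %d ids but %d are required (ratio %d x %d positives)",
      length(negative_pool), n_draw, ratio, n_pos),
      "psdosage_validation_error")
  }
  aucs <- vapply(seq_len(repeats), function(r) {
    neg <- withr::with_seed(derive_seed(seed, r), {
      sample(negative_pool, n_draw, replace = FALSE)
    })
    ids <- c(positives, neg)
    rank_auc(scores[ids], c(rep(1L, n_pos), rep(0L, n_draw)))
  }, numeric(1))
  structure(
    list(auc = aucs, mean_auc = mean(aucs), n_pos = n_pos,
         n_neg_per_repeat = n_draw, ratio = ratio, repeats = repeats,
         seed = seed),
    class = "ps_eval")
}

#' @export
print.ps_eval <- function(x, ...) {
  cat(sprintf(
    "Repeated-subsampling AUC: mean %.4f over %d repeats (%d pos, %d neg/repeat)\n",
    x$mean_auc, x$repeats, x$n_pos, x$n_neg_per_repeat))
  invisible(x)
}

#' @export
tidy.ps_eval <- function(x, ...) {
  tibble::tibble(repeat_id = seq_along(x$auc), auc = x$auc)
}

#' @export
glance.ps_eval <- function(x, ...) {
  tibble::tibble(mean_auc = x$mean_auc, sd_auc = stats::sd(x$auc),
                 n_pos = x$n_pos, n_neg_per_repeat = x$n_neg_per_repeat,
                 ratio = x$ratio, repeats = x$repeats, seed = x$seed)
}

#' Stratified k-fold assignment
#'
#' Ids are shuffled within each class under `seed` and dealt round-robin to
#' folds, so per-fold class counts differ from perfect proportionality by at
#' most one.
#'
#' @param ids Character or integer vector of example ids.
#' @param labels Class labels, same length as `ids`.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `label`, `fold`.
#' @export
kfold_splits <- function(ids, labels, k = 5, seed = 1) {
  if (length(ids) != length(labels)) {
    abort_ps("ids and labels must have equal length",
             "psdosage_validation_error")
  }
  if (k < 2) abort_ps("k must be >= 2", "psdosage_validation_error")
  tab <- table(labels)
  if (any(tab < k)) {
    abort_ps(sprintf("class '%s' has fewer members than k = %d",
                     names(tab)[which.min(tab)], k),
             "psdosage_validation_error")
  }
  fold <- integer(length(ids))
  withr::with_seed(derive_seed(seed, 1L), {
    for (cl in names(tab)) {
      pos <- which(labels == cl)
      pos <- pos[sample.int(length(pos))]
      fold[pos] <- rep_len(seq_len(k), length(pos))
    }
  })
  tibble::tibble(id = ids, label = labels, fold = fold)
}

#' Distance-to-median confounder normalization
#'
#' Removes the trend of a score along a confounding covariate: genes are
#' sorted by the covariate, overlapping windows of `window` genes advancing
#' by `step` are formed (the final window is anchored to the end so every
#' gene is covered), each window's median score is taken, a gene's rolling
#' median `rps` is the mean of the medians of all windows containing it, and
#' the DM value is `score - rps`. Rows come back in the caller's original
#' order.
#'
#' @param data Data frame with one row per gene.
#' @param score Column name (string) of the score to normalize.
#' @param covariate Column name (string) of the confounding covariate.
#' @param id Column name of the gene identifier (used for deterministic tie
#'   breaking).
#' @param window Genes per window (default 50).
#' @param step Genes by which adjacent windows advance; `window - step` genes
#'   overlap (defaults give a 50-gene window with 25-gene overlap).
#' @return The input tibble with added columns `rps` and `dm`.
#' @export
dm_normalize <- function(data, score, covariate, id = "gene_id",
                         window = 50, step = 25) {
  if (!all(c(score, covariate, id) %in% names(data))) {
    abort_ps("`score`, `covariate` and `id` must name columns of `data`",
             "psdosage_validation_error")
  }
  if (step >= window && nrow(data) > window) {
    abort_ps("window must be greater than step", "psdosage_validation_error")
  }
  n <- nrow(data)
  ord <- order(data[[covariate]], data[[id]])
  ps <- data[[score]][ord]
  if (n <= window) {
    starts <- 1L
  } else {
    starts <- seq(1L, n - window + 1L, by = step)
    if (starts[length(starts)] != n - window + 1L) {
      starts <- c(starts, n - window + 1L)
    }
  }
  win_len <- min(window, n)
  med <- vapply(starts, function(s) stats::median(ps[s:(s + win_len - 1L)]),
                numeric(1))
  rps_sum <- numeric(n)
  rps_cnt <- integer(n)
  for (w in seq_along(starts)) {
    idx <- starts[w]:(starts[w] + win_len - 1L)
    rps_sum[idx] <- rps_sum[idx] + med[w]
    rps_cnt[idx] <- rps_cnt[idx] + 1L
  }
  rps_sorted <- rps_sum / rps_cnt
  rps <- numeric(n)
  rps[ord] <- rps_sorted
  out <- tibble::as_tibble(data)
  out$rps <- rps
  out$dm <- out[[score]] - rps
  out
}
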