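# DosPS: phase-separation prediction from four gene-constraint scores
# (pLI, LOEUF, pHaplo, pTriplo) with L2-regularized logistic regression.
#
# The regression itself is fitted with glmnet (ridge); the sklearn-style
# inverse regularization strength C maps to glmnet's penalty via
# lambda = 1 / (n * C).

DOSPS_FEATURES <- c("pli", "loeuf", "phaplo", "ptriplo")

standardize_train <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  flat <- !is.finite(scale) | scale < 1e-12
  if (any(flat)) {
    rlang::warn(sprintf("constant feature(s) retained with unit scale: %s",
                        paste(colnames(x)[flat], collapse = ", ")))
    scale[flat] <- 1
  }
  list(center = center, scale = scale,
       z = sweep(sweep(x, 2, center), 2, scale, "/"))
}

fit_ridge_logistic <- function(z, y, C) {
  lam <- 1 / (nrow(z) * C)
  fit <- glmnet::glmnet(z, y, family = "binomial", alpha = 0,
                        lambda = lam, standardize = FALSE, thresh = 1e-10)
  list(weights = stats::setNames(as.numeric(fit$beta), colnames(z)),
       intercept = as.numeric(fit$a0), lambda = lam)
}

cv_auc_for <- function(z, y, C, k, seed) {
  folds <- kfold_splits(seq_len(nrow(z)), y, k = k, seed = seed)
  aucs <- vapply(seq_len(k), function(f) {
    te <- folds$fold == f
    m <- fit_ridge_logistic(z[!te, , drop = FALSE], y[!te], C)
    p <- as.numeric(z[te, , drop = FALSE] %*% m$weights + m$intercept)
    rank_auc(p, y[te])
  }, numeric(1))
  mean(aucs)
}

#' Fit the DosPS predictor
#'
#' Training pools both phase-separating classes (self-assembling and
#' partner-dependent) as positives, samples `neg_sample` non-phase-separating
#' genes without replacement as negatives, drops genes with any missing
#' feature, z-standardizes the four scores on the training rows, and fits an
#' L2-regularized logistic regression. The grid over the inverse
#' regularization strength `C` and over seeds is scored by stratified
#' `k`-fold cross-validated AUC on the training set and the best grid point
#' is refitted on all training rows. (The seed grid only moves fold
#' assignment and negative sampling; it mirrors tuning a solver's random
#' state and is retained for provenance.)
#'
#' @param scores Dosage-score table (schema `"dosage"`): `gene_id`, `pli`,
#'   `loeuf`, `phaplo`, `ptriplo`.
#' @param labels Label table with `id` and `class` columns; classes
#'   `"self-assembling"` and `"partner-dependent"` are positives, `"non-PS"`
#'   the negative pool. An optional `split` column restricts training to
#'   `split == "train"`.
#' @param grid Numeric vector of `C` values.
#' @param seeds Integer vector of candidate seeds.
#' @param neg_sample Number of negatives drawn for training (default 282).
#' @param seed Master seed for the negative draw.
#' @param k Folds for the selection criterion.
#' @return A `dosps_model` object.
#' @export
fit_dosps <- function(scores, labels, grid = c(0.01, 0.1, 1, 10, 100),
                      seeds = 1L, neg_sample = 282, seed = 1, k = 5) {
  if ("split" %in% names(labels)) {
    labels <- labels[labels$split == "train", , drop = FALSE]
  }
  pos_ids <- labels$id[labels$class %in% c("self-assembling",
                                           "partner-dependent")]
  neg_ids <- labels$id[labels$class == "non-PS"]
  if (length(neg_ids) < neg_sample) {
    abort_ps(sprintf("negative pool (%d) smaller than neg_sample (%d)",
                     length(neg_ids), neg_sample),
             "psdosage_validation_error")
  }
  neg_draw <- withr::with_seed(derive_seed(seed, 7L),
                               sample(neg_ids, neg_sample, replace = FALSE))
  train_ids <- c(pos_ids, neg_draw)
  df <- scores[match(train_ids, scores$gene_id), , drop = FALSE]
  y <- c(rep(1L, length(pos_ids)), rep(0L, length(neg_draw)))
  x <- as.matrix(df[, DOSPS_FEATURES])
  ok <- stats::complete.cases(x)
  x <- x[ok, , drop = FALSE]
  y <- y[ok]
  if (length(unique(y)) < 2) {
    abort_ps("a class emptied after dropping rows with missing features",
             "psdosage_validation_error")
  }
  st <- standardize_train(x)
  best <- NULL
  for (C in grid) for (s in seeds) {
    cv <- cv_auc_for(st$z, y, C, k, s)
    if (is.null(best) || cv > best$cv + 1e-12) {
      best <- list(C = C, seed = s, cv = cv)
    }
  }
  fit <- fit_ridge_logistic(st$z, y, best$C)
  structure(list(
    feature_names = DOSPS_FEATURES,
    weights = fit$weights, intercept = fit$intercept,
    center = st$center, scale = st$scale,
    C = best$C, lambda = fit$lambda, seed = best$seed,
    cv_auc = best$cv, n_train = length(y),
    metadata = list(n_pos = sum(y == 1), n_neg = sum(y == 0),
                    neg_sample = neg_sample, grid = grid,
                    seeds = seeds, master_seed = seed)
  ), class = "dosps_model")
}

#' Predict DosPS scores
#'
#' `sigmoid(w . z + b)` on features standardized with the training
#' parameters. Genes missing any feature receive `NA` with a reason column,
#' never an implicit zero.
#'
#' @param model A `dosps_model`.
#' @param scores Dosage-score table (schema `"dosage"`).
#' @return Tibble with `gene_id`, `dosps` (probability or `NA`), `reason`.
#' @export
predict_dosps <- function(model, scores) {
  x <- as.matrix(scores[, model$feature_names])
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  eta <- as.numeric(z %*% model$weights + model$intercept)
  p <- stats::plogis(eta)
  miss <- !stats::complete.cases(x)
  p[miss] <- NA_real_
  reason <- rep(NA_character_, nrow(scores))
  if (any(miss)) {
    reason[miss] <- apply(x[miss, , drop = FALSE], 1, function(r) {
      paste0("missing: ",
             paste(model$feature_names[is.na(r)], collapse = ","))
    })
  }
  tibble::tibble(gene_id = scores$gene_id, dosps = p, reason = reason)
}

#' @export
print.dosps_model <- function(x, ...) {
  cat("DosPS logistic model\n")
  cat(sprintf("  C = %g (lambda = %.3g), selection CV AUC = %.4f, n = %d\n",
              x$C, x$lambda, x$cv_auc, x$n_train))
  cat("  standardized weights:\n")
  for (f in x$feature_names) cat(sprintf("    %-8s %+0.4f\n", f, x$weights[[f]]))
  invisible(x)
}

#' @export
tidy.dosps_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$feature_names),
    estimate = c(x$intercept, unname(x$weights[x$feature_names])),
    center = c(NA, unname(x$center[x$feature_names])),
    scale = c(NA, unname(x$scale[x$feature_names])))
}

#' @export
glance.dosps_model <- function(x, ...) {
  tibble::tibble(C = x$C, lambda = x$lambda, cv_auc = x$cv_auc,
                 n_train = x$n_train, seed = x$seed)
}
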