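# Model serialization: JSON container recording feature order, preprocessing
# parameters, seed and training metadata, with the fitted model embedded
# (plain numbers for the logistic model, base64-encoded xgboost bytes for the
# tree ensemble). Save -> load roundtrips reproduce identical predictions.

MODEL_SERIALIZER_VERSION <- 1L

#' Save a fitted model to disk
#'
#' @param model A `dosps_model` or `truncps_model` object.
#' @param path Output path (JSON; written atomically).
#' @export
write_ps_model <- function(model, path) {
  payload <- if (inherits(model, "dosps_model")) {
    list(
      type = "dosps_logistic",
      serializer_version = MODEL_SERIALIZER_VERSION,
      feature_names = model$feature_names,
      model = list(
        feature_names_check = model$feature_names,
        weights = as.numeric(model$weights),
        intercept = model$intercept,
        center = as.numeric(model$center),
        scale = as.numeric(model$scale)
      ),
      C = model$C, lambda = model$lambda, seed = model$seed,
      cv_auc = model$cv_auc, n_train = model$n_train,
      metadata = model$metadata
    )
  } else if (inherits(model, "truncps_model")) {
    list(
      type = "truncps_xgboost",
      serializer_version = MODEL_SERIALIZER_VERSION,
      feature_names = model$feature_names,
      model = list(
        feature_names_check = model$feature_names,
        booster_raw = jsonlite::base64_enc(as.raw(model$booster_raw))
      ),
      params = model$params, nrounds = model$nrounds, seed = model$seed,
      metadata = model$metadata
    )
  } else {
    abort_ps("write_ps_model: model must be a dosps_model or truncps_model",
             "psdosage_validation_error")
  }
  write_atomic(path, function(tmp) {
    # digits = I(17): decimal text that reparses to the identical double
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = I(17))
  })
}

#' Load a model saved by [write_ps_model()]
#'
#' Validates the serializer version and cross-checks the recorded feature
#' order against the embedded model block; any mismatch (e.g. a permuted
#' feature list) raises an incompatibility error rather than returning a
#' silently wrong model. A truncated or malformed file raises a parse error
#' and never yields a partial model.
#'
#' @param path Path to a model JSON file.
#' @return The fitted model object.
#' @export
read_ps_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        abort_ps(sprintf("model parse error in %s: %s", path,
                                         conditionMessage(e)),
                                 "psdosage_parse_error")
                      })
  need <- c("type", "serializer_version", "feature_names", "model")
  if (!all(need %in% names(payload))) {
    abort_ps(sprintf("model parse error in %s: missing field(s) %s", path,
                     paste(setdiff(need, names(payload)), collapse = ", ")),
             "psdosage_parse_error")
  }
  if (payload$serializer_version != MODEL_SERIALIZER_VERSION) {
    abort_ps(sprintf("incompatible model file: serializer version %s (expected %d)",
                     payload$serializer_version, MODEL_SERIALIZER_VERSION),
             "psdosage_incompatible_model")
  }
  if (!identical(as.character(payload$feature_names),
                 as.character(payload$model$feature_names_check))) {
    abort_ps("incompatible model file: feature order does not match the embedded model",
             "psdosage_incompatible_model")
  }
  if (payload$type == "dosps_logistic") {
    fn <- as.character(payload$feature_names)
    structure(list(
      feature_names = fn,
      weights = stats::setNames(as.numeric(payload$model$weights), fn),
      intercept = as.numeric(payload$model$intercept),
      center = stats::setNames(as.numeric(payload$model$center), fn),
      scale = stats::setNames(as.numeric(payload$model$scale), fn),
      C = payload$C, lambda = payload$lambda, seed = payload$seed,
      cv_auc = payload$cv_auc, n_train = payload$n_train,
      metadata = payload$metadata
    ), class = "dosps_model")
  } else if (payload$type == "truncps_xgboost") {
    raw <- jsonlite::base64_dec(payload$model$booster_raw)
    structure(list(
      feature_names = as.character(payload$feature_names),
      booster_raw = raw,
      booster = xgboost::xgb.load.raw(raw),
      params = payload$params, nrounds = payload$nrounds,
      seed = payload$seed, metadata = payload$metadata
    ), class = "truncps_model")
  } else {
    abort_ps(sprintf("incompatible model file: unknown type '%s'", payload$type),
             "psdosage_incompatible_model")
  }
}
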