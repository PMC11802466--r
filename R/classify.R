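#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney concordance: the probability
#' that a random positive outscores a random negative, ties counting one
#' half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0))
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores)  # midranks implement the half-tie convention
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Train the final classifier
#'
#' Fits the gradient-boosted tree classifier on the full training set with
#' the tuned hyperparameters and the patterns surviving backward
#' elimination.
#'
#' @param patterns surviving patterns (non-empty, in order).
#' @param params an `hm_booster_params` (or compatible named list).
#' @param fm_train training feature matrix (columns = patterns).
#' @param labels_train balanced 0/1 training labels.
#' @param seed booster seed.
#' @param sample_id optional identifier of the training sample.
#' @return an `hm_model`.
#' @export
train_final <- function(patterns, params, fm_train, labels_train,
                        seed = 1L, sample_id = NULL) {
  if (length(patterns) == 0L) stop("need at least one pattern")
  stopifnot(ncol(fm_train) == length(patterns))
  colnames(fm_train) <- paste0("pattern_", seq_along(patterns))
  booster <- fit_booster(
    fm_train, labels_train, nrounds = params$nrounds %||% 50L,
    eta = params$eta %||% 0.2, max_depth = params$max_depth,
    min_child_weight = params$min_child_weight,
    subsample = params$subsample,
    colsample_bytree = params$colsample_bytree, seed = seed
  )
  structure(list(booster = booster, patterns = patterns, params = params,
                 feature_names = colnames(fm_train), seed = as.integer(seed),
                 sample_id = sample_id),
            class = "hm_model")
}

#' @export
print.hm_model <- function(x, ...) {
  cat("<hm_model> ", length(x$patterns), " patterns, ",
      x$params$nrounds %||% 50L, " boosting rounds",
      if (!is.null(x$sample_id)) paste0(", sample ", x$sample_id),
      "\n", sep = "")
  invisible(x)
}

#' Predict expression class probabilities
#'
#' @param object an `hm_model`.
#' @param newdata an `hm_profiles` object (pattern counts are recomputed)
#'   or a precomputed feature matrix with one column per model pattern.
#' @param type `"prob"` for probabilities, `"margin"` for log-odds.
#' @param ... unused.
#' @return numeric vector of scores, named by gene.
#' @export
predict.hm_model <- function(object, newdata, type = c("prob", "margin"), ...) {
  type <- match.arg(type)
  fm <- model_feature_matrix(object, newdata)
  X <- fm
  storage.mode(X) <- "double"
  out <- stats::predict(object$booster, X,
                        outputmargin = identical(type, "margin"))
  names(out) <- rownames(fm)
  out
}

model_feature_matrix <- function(model, newdata) {
  if (inherits(newdata, "hm_profiles")) {
    fm <- build_feature_matrix(newdata, model$patterns)
  } else {
    fm <- as.matrix(newdata)
    if (ncol(fm) != length(model$patterns)) {
      stop("feature matrix has ", ncol(fm), " columns but the model expects ",
           length(model$patterns))
    }
  }
  colnames(fm) <- model$feature_names
  fm
}

#' Evaluate a model on labelled profiles
#'
#' @param model an `hm_model`.
#' @param profiles `hm_profiles` (or a feature matrix) for the evaluation
#'   genes.
#' @param labels their 0/1 labels.
#' @return list with `auc` and the per-gene `scores`.
#' @export
evaluate_model <- function(model, profiles, labels) {
  scores <- stats::predict(model, profiles)
  list(auc = auc(scores, labels), scores = scores)
}

#' Apply a trained model to another sample
#'
#' Recomputes the training sample's pattern frequencies on the target
#' sample's profiles and scores them with the unchanged model - no new
#' tuning or elimination.  The target profiles must carry at least the
#' marks the model's patterns address.
#'
#' @param model an `hm_model` trained on sample A.
#' @param profiles_b,labels_b the target sample's profiles and labels.
#' @return list with `auc` and `scores`.
#' @export
cross_sample_apply <- function(model, profiles_b, labels_b) {
  marks_b <- dimnames(profiles_b)[[2L]]
  need <- max(vapply(model$patterns, function(p) p$mark, integer(1)))
  if (need > length(marks_b)) {
    stop("target sample lacks mark index ", need, " required by the model")
  }
  evaluate_model(model, profiles_b, labels_b)
}

#' Cross-sample transfer matrix
#'
#' Entry (i, j) is the AUC of sample i's model applied to sample j's test
#' genes; the diagonal reproduces the within-sample evaluations.
#'
#' @param models list of `hm_model`s.
#' @param test_sets list (same length) of `list(profiles, labels)`.
#' @return numeric matrix, models x samples.
#' @export
transfer_matrix <- function(models, test_sets) {
  k <- length(models)
  stopifnot(length(test_sets) == k)
  out <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      out[i, j] <- cross_sample_apply(models[[i]], test_sets[[j]]$profiles,
                                      test_sets[[j]]$labels)$auc
    }
  }
  out
}

#' One-sided paired comparison of AUC vectors
#'
#' Wilcoxon signed-rank test (normal approximation with continuity
#' correction) of the alternative "method b scores higher than method a",
#' pairing by sample.  Zero differences are dropped before ranking.
#'
#' @param auc_a,auc_b paired AUC vectors (length >= 5).
#' @return one-sided p-value.
#' @export
compare_paired_auc <- function(auc_a, auc_b) {
  if (length(auc_a) != length(auc_b)) stop("AUC vectors differ in length")
  if (length(auc_a) < 5L) stop("need at least 5 paired samples")
  if (all(auc_b - auc_a == 0)) stop("all paired differences are zero")
  stats::wilcox.test(auc_b, auc_a, paired = TRUE, alternative = "greater",
                     exact = FALSE, correct = TRUE)$p.value
}

#' Save / load a trained model
#'
#' JSON container holding the hyperparameters, the patterns, the training
#' seed and the serialized booster; reloading reproduces predictions
#' bit-exactly.
#'
#' @param model an `hm_model`.
#' @param path file path.
#' @return `load_model()` returns the `hm_model`.
#' @export
save_model <- function(model, path) {
  raw <- xgboost::xgb.save.raw(model$booster)
  obj <- list(
    format = "hm_model-1",
    sample_id = model$sample_id,
    seed = model$seed,
    params = unclass(model$params),
    feature_names = model$feature_names,
    patterns = lapply(model$patterns, function(p) {
      list(mark = p$mark, mark_name = p$mark_name, shape = p$shape,
           cutoff = p$cutoff)
    }),
    booster_raw = jsonlite::base64_enc(raw)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  booster <- xgboost::xgb.load.raw(jsonlite::base64_dec(obj$booster_raw))
  patterns <- lapply(obj$patterns, function(p) {
    hm_pattern(p$mark, unlist(p$shape), p$cutoff,
               mark_name = p$mark_name %||% NULL)
  })
  params <- lapply(obj$params, function(v) if (is.list(v)) unlist(v) else v)
  structure(list(booster = booster, patterns = patterns,
                 params = structure(params, class = "hm_booster_params"),
                 feature_names = unlist(obj$feature_names),
                 seed = obj$seed %||% NA_integer_,
                 sample_id = obj$sample_id %||% NULL),
            class = "hm_model")
}
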