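#' Run the full pattern-learning pipeline on one sample
#'
#' Convenience wrapper chaining the four stages: pattern extraction on the
#' training genes, backward elimination against the validation genes,
#' hyperparameter tuning, and the final fit.  Returns everything needed
#' for evaluation, transfer and explanation.
#'
#' @param profiles `hm_profiles` for all genes of the sample.
#' @param labels named 0/1 labels for the same genes.
#' @param split an [split_genes()] result; when `NULL` a split is drawn
#'   from `seed` with `n_train` covering half the genes (rounded down to
#'   an even count).
#' @param config an [extraction_config()]; its seed is taken from `seed`
#'   unless supplied explicitly.
#' @param seed master seed for split, extraction, tuning and final fit.
#' @param sample_id optional sample identifier stored in the model.
#' @return an `hm_fit` list: `model`, `extraction`, `elimination`,
#'   `tuning`, `split`, and `test_auc` with per-gene `test_scores`.
#' @export
run_pipeline <- function(profiles, labels, split = NULL, config = NULL,
                         seed = 1L, sample_id = NULL) {
  stopifnot(inherits(profiles, "hm_profiles"))
  genes <- dimnames(profiles)[[1L]]
  if (is.null(names(labels))) names(labels) <- genes
  if (is.null(split)) {
    n_train <- (length(genes) %/% 4L) * 2L
    split <- split_genes(genes, n_train = n_train, seed = seed)
  }
  if (is.null(config)) config <- extraction_config(seed = seed)

  sub_prof <- function(ids) {
    hm_profiles(unclass(profiles)[ids, , , drop = FALSE])
  }
  prof_train <- sub_prof(split$train)
  lab_train <- labels[split$train]
  lab_valid <- labels[split$valid]
  lab_test <- labels[split$test]

  degenerate_fit <- function(extraction, elim) {
    warning("no pattern survived; returning a chance-level fit")
    scores <- stats::setNames(rep(0.5, length(split$test)), split$test)
    structure(list(model = NULL, extraction = extraction,
                   elimination = elim, tuning = NULL, split = split,
                   test_auc = auc(scores, lab_test), test_scores = scores),
              class = "hm_fit")
  }

  extraction <- extract_features(prof_train, lab_train, config)
  if (length(extraction$patterns) == 0L) {
    return(degenerate_fit(extraction, NULL))
  }
  fm_train <- extraction$feature_matrix
  fm_valid <- build_feature_matrix(sub_prof(split$valid), extraction$patterns)

  elim <- backward_eliminate(extraction$patterns, fm_train, lab_train,
                             fm_valid, lab_valid,
                             booster = config$booster, seed = config$seed)
  if (length(elim$patterns) == 0L) {
    return(degenerate_fit(extraction, elim))
  }
  fm_train_be <- fm_train[, elim$keep, drop = FALSE]
  fm_valid_be <- fm_valid[, elim$keep, drop = FALSE]

  tune_ctl <- config$pso
  tune_ctl$seed <- config$seed + 900001L
  tune_ctl$value_to_reach <- -1  # AUC 1 on validation: cannot improve further
  tuning <- tune_hyperparameters(fm_train_be, lab_train, fm_valid_be,
                                 lab_valid, control = tune_ctl,
                                 seed = config$seed)

  model <- train_final(elim$patterns, tuning$params, fm_train_be, lab_train,
                       seed = config$seed, sample_id = sample_id)
  prof_test <- sub_prof(split$test)
  ev <- evaluate_model(model, prof_test, lab_test)

  structure(list(model = model, extraction = extraction, elimination = elim,
                 tuning = tuning, split = split, test_auc = ev$auc,
                 test_scores = ev$scores),
            class = "hm_fit")
}

#' @export
print.hm_fit <- function(x, ...) {
  cat("<hm_fit> ", length(x$extraction$patterns), " extracted -> ",
      length(x$model$patterns), " surviving patterns; test AUC ",
      format(x$test_auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Subset an `hm_profiles` object by gene ids
#'
#' @param profiles an `hm_profiles`.
#' @param gene_ids character vector of gene ids to keep (order preserved).
#' @return an `hm_profiles` with the selected genes.
#' @export
subset_profiles <- function(profiles, gene_ids) {
  missing <- setdiff(gene_ids, dimnames(profiles)[[1L]])
  if (length(missing)) {
    stop("genes not in profiles: ", paste(utils::head(missing, 3L),
                                          collapse = ", "))
  }
  hm_profiles(unclass(profiles)[gene_ids, , , drop = FALSE])
}
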