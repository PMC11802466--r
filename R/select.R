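#' Backward elimination of redundant patterns
#'
#' Starting from the full accepted pattern set, repeatedly and transiently
#' removes patterns walking from the last-added towards the first.  A
#' transient removal becomes permanent when the validation AUC (booster
#' trained on the training set with the reduced feature set) is equal to or
#' greater than the best AUC seen so far; the walk then restarts from the
#' (new) last pattern.  The scan ends after a complete pass without a
#' removal.  The memorized validation AUC can therefore only go up.
#'
#' @param patterns accepted patterns, in acceptance order.
#' @param fm_train,labels_train training feature matrix and labels.
#' @param fm_valid,labels_valid validation feature matrix and labels.
#' @param booster scoring-booster settings (`nrounds`, `eta`), the same
#'   fixed settings used during extraction.
#' @param seed booster seed.
#' @return list with `patterns` (survivors, original relative order),
#'   `keep` (their indices into the input list), `best_auc`, and `trace`
#'   (one row per transient evaluation).
#' @export
backward_eliminate <- function(patterns, fm_train, labels_train,
                               fm_valid, labels_valid,
                               booster = list(nrounds = 50L, eta = 0.2),
                               seed = 1L) {
  if (length(patterns) < 1L) stop("need at least one pattern")
  stopifnot(ncol(fm_train) == length(patterns),
            ncol(fm_valid) == length(patterns))

  eval_set <- function(cols) {
    if (length(cols) == 0L) return(0.5)
    m <- fit_booster(fm_train[, cols, drop = FALSE], labels_train,
                     nrounds = booster$nrounds, eta = booster$eta,
                     seed = seed)
    auc(booster_scores(m, fm_valid[, cols, drop = FALSE]), labels_valid)
  }

  live <- seq_along(patterns)
  best <- eval_set(live)
  trace <- list(data.frame(step = 0L, removed = NA_integer_,
                           n_live = length(live), auc = best,
                           permanent = FALSE))
  pos <- length(live)
  step <- 0L
  while (pos >= 1L && length(live) > 0L) {
    step <- step + 1L
    cand <- live[-pos]
    a <- eval_set(cand)
    permanent <- a >= best
    trace[[step + 1L]] <- data.frame(step = step, removed = live[pos],
                                     n_live = length(cand), auc = a,
                                     permanent = permanent)
    if (permanent) {
      live <- cand
      best <- a
      pos <- length(live)
    } else {
      pos <- pos - 1L
    }
  }
  if (length(live) == 0L) {
    warning("backward elimination removed every pattern")
  }
  list(patterns = patterns[live], keep = live, best_auc = best,
       trace = do.call(rbind, trace))
}

#' Tuning box for the final classifier's hyperparameters
#'
#' Six hyperparameters are tuned: boosting rounds, shrinkage (eta), maximum
#' tree depth, minimum child weight, and the row/column subsample
#' fractions.  Integer parameters range over half-open cells so flooring
#' reaches every value including the endpoints, mirroring
#' [particle_bounds()].
#'
#' @return data.frame with columns `param`, `lower`, `upper`, `integer`.
#' @export
booster_param_box <- function() {
  data.frame(
    param = c("nrounds", "eta", "max_depth", "min_child_weight",
              "subsample", "colsample_bytree"),
    lower = c(10, 0.01, 2, 1, 0.5, 0.5),
    upper = c(301, 0.5, 11, 10, 1, 1),
    integer = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Decode a tuning-particle position into hyperparameters
#'
#' @param x numeric vector over the [booster_param_box()] box.
#' @param box the parameter box.
#' @return named list of class `hm_booster_params`.
#' @export
decode_booster_params <- function(x, box = booster_param_box()) {
  stopifnot(length(x) == nrow(box))
  out <- as.list(pmin(pmax(x, box$lower), box$upper))
  names(out) <- box$param
  for (i in which(box$integer)) {
    out[[i]] <- decode_int(x[i], box$lower[i], box$upper[i] - 1L)
  }
  structure(out, class = "hm_booster_params")
}

#' @export
print.hm_booster_params <- function(x, ...) {
  cat("<hm_booster_params>\n")
  for (nm in names(x)) cat("  ", nm, ": ", format(x[[nm]], digits = 4),
                           "\n", sep = "")
  invisible(x)
}

#' Tune the final classifier's hyperparameters with SPSO2007
#'
#' Minimizes the negative validation AUC of a booster trained on the
#' training features over the [booster_param_box()] box.  One particle of
#' the initial swarm is pinned at the box center so the tuned result can
#' never fall below the center-default configuration.
#'
#' @param fm_train,labels_train training feature matrix (surviving
#'   patterns) and labels.
#' @param fm_valid,labels_valid validation data.
#' @param control a [pso_control()]; its `seed` makes tuning reproducible.
#' @param box parameter box, see [booster_param_box()].
#' @param seed booster seed used inside the objective.
#' @return list with `params` (an `hm_booster_params`), `best_auc`, and
#'   the swarm `trace`.
#' @export
tune_hyperparameters <- function(fm_train, labels_train, fm_valid,
                                 labels_valid,
                                 control = pso_control(max_iter = 25L,
                                                       max_stagnant = 8L,
                                                       seed = 1L),
                                 box = booster_param_box(), seed = 1L) {
  if (ncol(fm_train) < 1L) stop("need at least one surviving pattern")
  objective <- function(x) {
    p <- decode_booster_params(x, box)
    m <- fit_booster(fm_train, labels_train, nrounds = p$nrounds,
                     eta = p$eta, max_depth = p$max_depth,
                     min_child_weight = p$min_child_weight,
                     subsample = p$subsample,
                     colsample_bytree = p$colsample_bytree, seed = seed)
    -auc(booster_scores(m, fm_valid), labels_valid)
  }
  if (is.null(control$init)) {
    control$init <- matrix((box$lower + box$upper) / 2, nrow = 1L)
  }
  res <- pso_minimize(objective, box$lower, box$upper, control)
  list(params = decode_booster_params(res$par, box), best_auc = -res$value,
       trace = res$trace, evals = res$evals)
}
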