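# Shared gradient-boosted tree fitting.  base_score is pinned at 0.5 so the
# model's base log-odds is exactly 0, which the per-prediction log-odds
# decomposition relies on; nthread = 1 keeps fits bit-reproducible.
fit_booster <- function(X, y, nrounds = 50L, eta = 0.2, max_depth = NULL,
                        min_child_weight = NULL, subsample = NULL,
                        colsample_bytree = NULL, seed = 1L) {
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  params <- list(objective = "binary:logistic", eta = eta, nthread = 1L,
                 base_score = 0.5, seed = as.integer(seed))
  if (!is.null(max_depth)) params$max_depth <- as.integer(max_depth)
  if (!is.null(min_child_weight)) params$min_child_weight <- min_child_weight
  if (!is.null(subsample)) params$subsample <- subsample
  if (!is.null(colsample_bytree)) params$colsample_bytree <- colsample_bytree
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = as.integer(nrounds), verbose = 0L)
}

# Booster scores for a feature matrix; constant 0.5 for a 0-column matrix
# (no features means no information).
booster_scores <- function(booster, X) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) return(rep(0.5, nrow(X)))
  storage.mode(X) <- "double"
  stats::predict(booster, X)
}
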