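# Independent, deliberately naive reference implementations used as
# oracles, plus small cached fixtures shared across test files.

naive_window_corr <- function(x, shape) {
  L <- length(shape)
  vapply(seq_len(length(x) - L + 1L), function(p) {
    win <- x[p:(p + L - 1L)]
    if (stats::sd(win) == 0) return(NA_real_)
    suppressWarnings(stats::cor(win, shape))
  }, numeric(1))
}

naive_match_count <- function(x, pattern) {
  r <- naive_window_corr(x, pattern$shape)
  sum(r > pattern$cutoff, na.rm = TRUE)
}

naive_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Exact one-sided signed-rank p-value by enumerating all sign assignments.
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  mean(w_all >= w_obs)
}

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

# Small planted-motif dataset for fast module tests.
tiny_dataset <- function() {
  fixture("tiny", function() generate_dataset(sim_config(n_genes = 200L,
                                                         seed = 123L)))
}

# A small trained model on the tiny dataset (single true-motif pattern
# plus one noise pattern), for classify/explain tests.
tiny_model <- function() {
  fixture("tiny_model", function() {
    ds <- tiny_dataset()
    pats <- list(
      hm_pattern(1, ds$config$motif_shape, 0.95, mark_name = "H3K4me3"),
      hm_pattern(2, c(0.1, 0.9, 0.4), 0.8, mark_name = "H3K4me1")
    )
    fm <- build_feature_matrix(ds$profiles, pats)
    params <- structure(list(nrounds = 30L, eta = 0.2, max_depth = 4L),
                        class = "hm_booster_params")
    list(model = train_final(pats, params, fm, ds$labels, seed = 5L),
         fm = fm, ds = ds, patterns = pats)
  })
}
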