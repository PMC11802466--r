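# Independent oracle: recompute one gene's per-feature contributions
# directly from the dumped tree table, using its own bottom-up pass.
oracle_contributions <- function(model, x) {
  tt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model$booster))
  contrib <- stats::setNames(numeric(length(model$feature_names)),
                             model$feature_names)
  intercept <- 0
  for (tr_id in unique(tt$Tree)) {
    tr <- tt[tt$Tree == tr_id, ]
    expected <- function(id) {
      row <- tr[tr$ID == id, ]
      if (row$Feature == "Leaf") return(row$Gain)
      y <- tr[tr$ID == row$Yes, ]
      n <- tr[tr$ID == row$No, ]
      (expected(row$Yes) * y$Cover + expected(row$No) * n$Cover) /
        (y$Cover + n$Cover)
    }
    id <- tr$ID[tr$Node == 0]
    intercept <- intercept + expected(id)
    repeat {
      row <- tr[tr$ID == id, ]
      if (row$Feature == "Leaf") break
      nxt <- if (x[[row$Feature]] < row$Split) row$Yes else row$No
      contrib[row$Feature] <- contrib[row$Feature] +
        expected(nxt) - expected(id)
      id <- nxt
    }
  }
  list(intercept = intercept, contributions = contrib)
}

test_that("a depth-1 stump decomposes into leaf minus cover-weighted mean", {
  n <- 40L
  labels <- rep(c(0L, 1L), n / 2)
  fm <- matrix(labels * 4L, ncol = 1L, dimnames = list(NULL, NULL))
  m <- train_final(list(hm_pattern(1, c(0.2, 0.8), 0.8)),
                   list(nrounds = 1L, eta = 0.3, max_depth = 1L),
                   fm, labels)
  tt <- as.data.frame(xgboost::xgb.model.dt.tree(model = m$booster))
  leaves <- tt[tt$Feature == "Leaf", ]
  root_e <- sum(leaves$Gain * leaves$Cover) / sum(leaves$Cover)

  ex <- decompose_prediction(m, 4)  # routed to the high-count leaf
  hi_leaf <- leaves$Gain[which.max(leaves$Gain)]
  expect_equal(unname(ex$contributions[1L]), hi_leaf - root_e,
               tolerance = 1e-9)
  expect_equal(ex$intercept, root_e, tolerance = 1e-9)
})

test_that("intercept plus contributions reproduce every logit", {
  tm <- tiny_model()
  ex <- explain_genes(tm$model, tm$fm)
  # the decomposition identity is exact in double precision
  expect_equal(ex$logit, ex$intercept + rowSums(ex$contributions))
  # the model itself reports float32 margins, so compare at that
  # resolution on the log-odds scale and at 1e-6 on the probability scale
  margins <- predict(tm$model, tm$fm, type = "margin")
  expect_lt(max(abs(ex$logit - margins)), 1e-5)
  expect_lt(max(abs(ex$prob - predict(tm$model, tm$fm))), 1e-6)
})

test_that("the path decomposition matches a brute-force tree walk", {
  ds <- tiny_dataset()
  pats <- list(hm_pattern(1, ds$config$motif_shape, 0.95),
               hm_pattern(3, c(0.8, 0.2, 0.6), 0.7))
  fm <- build_feature_matrix(ds$profiles, pats)
  m <- train_final(pats, list(nrounds = 8L, eta = 0.3, max_depth = 3L),
                   fm, ds$labels, seed = 9L)
  ex <- explain_genes(m, fm)
  for (g in c(1L, 7L, 50L, 140L)) {
    o <- oracle_contributions(m, as.list(stats::setNames(fm[g, ],
                                                         m$feature_names)))
    expect_equal(unname(ex$contributions[g, ]), unname(o$contributions),
                 tolerance = 1e-8)
    expect_equal(ex$intercept, o$intercept, tolerance = 1e-8)
  }
  expect_error(decompose_prediction(m, c(1, 2, 3)), "does not match")
})

test_that("importance maps concentrate on matched bins and sum to one", {
  # every gene carries the motif at bins 30..32; high-expression genes
  # carry a second copy at bins 40..42, so the count separates classes
  n <- 60L
  shape <- c(0.1, 0.9, 0.3)
  arr <- array(0.2, dim = c(n, 2, 60),
               dimnames = list(sprintf("g%02d", 1:n), c("m1", "m2"), NULL))
  labels <- rep(c(0L, 1L), n / 2)
  for (g in 1:n) {
    arr[g, 1, 30:32] <- 0.2 + 5 * shape
    if (labels[g] == 1L) arr[g, 1, 40:42] <- 0.2 + 5 * shape
  }
  prof <- hm_profiles(arr)
  pats <- list(hm_pattern(1, shape, 0.9))
  fm <- build_feature_matrix(prof, pats)
  expect_identical(unname(fm[, 1L]), labels + 1L)
  m <- train_final(pats, list(nrounds = 10L, eta = 0.3), fm, labels,
                   seed = 2L)
  imp <- bin_importance(m, prof)
  expect_equal(sum(imp), 1)
  expect_true(all(imp >= 0))
  expect_true(all(which(imp[1L, ] > 0) %in% c(30:32, 40:42)))
  expect_identical(sum(imp[2L, ]), 0)
  # a match's contribution spreads uniformly over its bins
  expect_equal(imp[1L, 30L], imp[1L, 31L])
  expect_equal(imp[1L, 31L], imp[1L, 32L])
})

test_that("frequency-contribution correlations carry the right signs", {
  counts <- matrix(c(0:9, rep(3, 10)), ncol = 2L,
                   dimnames = list(NULL, c("pattern_1", "pattern_2")))
  contribs <- cbind(2 * counts[, 1L] + 1, seq(0, 1, length.out = 10))
  pats <- list(hm_pattern(1, c(0.2, 0.8), 0.8),
               hm_pattern(4, c(0.2, 0.8), 0.8))
  expect_message(
    res <- contribution_frequency_correlation(contribs, counts, pats),
    "constant frequency")
  expect_identical(res$skipped, 2L)
  expect_equal(res$per_pattern$rho, 1)
  expect_identical(res$per_pattern$mark, 1L)

  contribs2 <- cbind(-3 * counts[, 1L], counts[, 1L])
  counts2 <- cbind(counts[, 1L], counts[, 1L])
  res2 <- contribution_frequency_correlation(contribs2, counts2, pats)
  expect_equal(res2$per_pattern$rho, c(-1, 1))
  expect_identical(nrow(res2$per_mark), 2L)
})

test_that("waterfall tables order by importance and end at the prediction", {
  tm <- tiny_model()
  ex <- decompose_prediction(tm$model, tm$fm[5L, ], gene_id = "gene_0005")
  wf <- waterfall_data(ex)
  expect_identical(wf$feature[1L], "intercept")
  body <- wf[-1L, ]
  expect_true(all(diff(abs(body$contribution)) <= 0))
  expect_equal(wf$cumulative_prob[nrow(wf)], ex$prob, tolerance = 1e-12)
})
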