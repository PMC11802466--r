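test_that("generation is deterministic and labels are balanced", {
  cfg <- sim_config(n_genes = 300L, seed = 77L)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(unclass(d1$profiles), unclass(d2$profiles))
  expect_identical(d1$ledger, d2$ledger)
  expect_lte(abs(sum(d1$labels == 1L) - sum(d1$labels == 0L)), 1L)
  # strong class separation in expression: median split recovers the
  # intended class of every gene at this seed
  expect_identical(unname(d1$labels), d1$intended)
})

test_that("ledger counts follow the class-conditional Poisson design", {
  ds <- fixture("big_sim", function() generate_dataset(sim_config(seed = 500L)))
  per_gene <- as.vector(table(factor(ds$ledger$gene_id,
                                     levels = names(ds$labels))))
  hi <- per_gene[ds$intended == 1L]
  lo <- per_gene[ds$intended == 0L]
  se_hi <- stats::sd(hi) / sqrt(length(hi))
  se_lo <- stats::sd(lo) / sqrt(length(lo))
  expect_lt(abs(mean(hi) - ds$config$lambda_high), 3 * se_hi)
  expect_lt(abs(mean(lo) - ds$config$lambda_low), 3 * se_lo)
})

test_that("a null configuration plants no class difference", {
  expect_message(cfg <- sim_config(n_genes = 600L, lambda_high = 2,
                                   lambda_low = 2, seed = 9L),
                 "null dataset")
  ds <- generate_dataset(cfg)
  per_gene <- as.vector(table(factor(ds$ledger$gene_id,
                                     levels = names(ds$labels))))
  hi <- per_gene[ds$intended == 1L]
  lo <- per_gene[ds$intended == 0L]
  se <- sqrt(stats::var(hi) / length(hi) + stats::var(lo) / length(lo))
  expect_lt(abs(mean(hi) - mean(lo)), 3 * se)
})

test_that("rescanning profiles with the true motif recovers the ledger", {
  ds <- fixture("big_sim", function() generate_dataset(sim_config(seed = 500L)))
  truth <- hm_pattern(ds$config$motif_mark, ds$config$motif_shape, 0.95)
  P <- mark_matrix(ds$profiles, ds$config$motif_mark)
  found <- 0L
  for (i in seq_len(nrow(ds$ledger))) {
    g <- match(ds$ledger$gene_id[i], rownames(P))
    if (ds$ledger$start[i] %in% match_positions(P[g, ], truth)) {
      found <- found + 1L
    }
  }
  expect_gte(found / nrow(ds$ledger), 0.95)
})

test_that("amplitude rescaling leaves match counts unchanged", {
  ds <- tiny_dataset()
  truth <- hm_pattern(1, ds$config$motif_shape, 0.9)
  row <- mark_matrix(ds$profiles, 1)[4L, ]
  expect_identical(match_count(10 * row, truth), match_count(row, truth))
})

test_that("paired samples share or differ in motif as requested", {
  base <- sim_config(n_genes = 100L, seed = 31L)
  expect_error(make_paired_samples(base, 1L), ">= 2")
  shared <- make_paired_samples(base, 2L, shared_motif = TRUE)
  expect_identical(shared[[1L]]$config$motif_shape,
                   shared[[2L]]$config$motif_shape)
  expect_false(identical(unclass(shared[[1L]]$profiles),
                         unclass(shared[[2L]]$profiles)))
  unshared <- make_paired_samples(base, 2L, shared_motif = FALSE)
  expect_false(identical(unshared[[1L]]$config$motif_shape,
                         unshared[[2L]]$config$motif_shape))
  expect_gt(stats::sd(unshared[[2L]]$config$motif_shape), 0)
})

test_that("impossible placements are rejected", {
  expect_error(sim_config(motif_shape = runif(8), placement = c(-5L, -1L)),
               "narrower")
})

test_that("pattern recovery scores lag-shifted detectors highly", {
  motif <- c(0.05, 0.95, 0.05, 0.9, 0.1, 0.85)
  expect_equal(pattern_recovery(motif, motif), 1)
  # the same alternation one bin out of phase is still the motif
  lagged <- c(0.95, 0.05, 0.9, 0.1, 0.85, 0.05)
  expect_gt(pattern_recovery(lagged, motif), 0.9)
  # an unrelated monotone ramp is not
  expect_lt(pattern_recovery(seq(0, 1, length.out = 6), motif), 0.8)
})
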