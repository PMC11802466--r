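test_that("particle decoding reaches every mark and length", {
  b <- particle_bounds()
  x <- c(1, 2, 0.7, runif(8))
  expect_identical(length(decode_particle(x)$shape), 2L)  # lower bound of L
  x[2] <- b$upper[2]
  expect_identical(length(decode_particle(x)$shape), 8L)
  marks <- vapply(1:5, function(m) {
    decode_particle(c(m + 0.5, 4, 0.7, runif(8)))$mark
  }, integer(1))
  expect_identical(marks, 1:5)  # equispaced midpoints hit each mark once
})

test_that("decoding is total on the box and always yields valid patterns", {
  set.seed(31)
  b <- particle_bounds()
  for (i in 1:10000) {
    x <- runif(11, b$lower, b$upper)
    p <- decode_particle(x)
    expect_s3_class(p, "hm_pattern")
  }
  # constant-shape corner: still decodes to a valid (non-constant) pattern
  p <- decode_particle(c(1, 5, 0.8, rep(0.5, 8)))
  expect_gt(stats::sd(p$shape), 0)
  p0 <- decode_particle(c(1, 5, 0.8, rep(0, 8)))
  expect_gt(stats::sd(p0$shape), 0)
})

test_that("candidate scoring rewards separation and degrades to chance", {
  # profiles where exactly the high-label genes carry the motif once
  n <- 60L
  arr <- array(0.2, dim = c(n, 1, 40),
               dimnames = list(sprintf("g%02d", 1:n), "m1", NULL))
  shape <- c(0.1, 0.9, 0.2, 0.8)
  labels <- rep(c(1L, 0L), each = n / 2)
  for (g in which(labels == 1L)) arr[g, 1, 10:13] <- shape
  prof <- hm_profiles(arr)
  pat <- hm_pattern(1, shape, 0.9)
  expect_identical(score_candidate(pat, prof, labels), 1.0)

  # a pattern that never matches the flat background: chance level
  miss <- hm_pattern(1, c(0.9, 0.1, 0.9), 0.95)
  flat <- hm_profiles(array(1, dim = c(n, 1, 40),
                            dimnames = list(sprintf("g%02d", 1:n), "m1",
                                            NULL)))
  expect_identical(score_candidate(miss, flat, labels), 0.5)
})

test_that("the planted shape outscores random candidate patterns", {
  ds <- tiny_dataset()
  truth <- hm_pattern(1, ds$config$motif_shape, 0.95)
  s_truth <- score_candidate(truth, ds$profiles, ds$labels, seed = 2L)
  set.seed(17)
  s_rand <- vapply(1:20, function(i) {
    p <- decode_particle(c(runif(1, 1, 6), runif(1, 2, 9),
                           runif(1, 0.5, 0.99), runif(8)))
    score_candidate(p, ds$profiles, ds$labels, seed = 2L)
  }, numeric(1))
  expect_true(all(s_truth > s_rand))
})

test_that("extraction terminates, accepts monotonically and is reproducible", {
  ds <- tiny_dataset()
  quick <- extraction_config(max_rounds = 3L, max_stagnant_rounds = 2L,
                             subset_size = 3000L,
                             pso = pso_control(max_iter = 4L,
                                               max_stagnant = 3L),
                             seed = 11L)
  ex1 <- extract_features(ds$profiles, ds$labels, quick)
  acc <- ex1$trace$best_auc[ex1$trace$accepted]
  expect_true(all(diff(acc) > 0))  # strict improvement on acceptance
  expect_identical(ncol(ex1$feature_matrix), length(ex1$patterns))

  ex2 <- extract_features(ds$profiles, ds$labels, quick)
  expect_equal(ex1$patterns, ex2$patterns)
  expect_identical(ex1$feature_matrix, ex2$feature_matrix)

  # a trivially low AUC target stops after the first accepted round
  one <- extract_features(ds$profiles, ds$labels,
                          extraction_config(auc_target = 0,
                                            max_rounds = 10L,
                                            pso = pso_control(max_iter = 2L,
                                                              max_stagnant = 2L),
                                            seed = 12L))
  expect_identical(nrow(one$trace), 1L)
  expect_lte(length(one$patterns), 1L)
})
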