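test_that("binning yields the right geometry and per-bin means", {
  const_track <- data.frame(chrom = "chr1", start = 0L, end = 20000L,
                            value = 2.0)
  bins <- bin_signal(const_track, "chr1", tss = 10000L)
  expect_length(bins, 200L)
  expect_true(all(bins == 2.0))
  expect_identical(names(bins)[1], "bin_-100")
  expect_identical(names(bins)[200], "bin_100")

  # per-base ramp track: value at base i is i; oracle computes each bin
  # mean by a plain loop over bases
  ramp <- data.frame(chrom = "chr1", start = 0:9999, end = 1:10000,
                     value = as.numeric(0:9999))
  bins <- bin_signal(ramp, "chr1", tss = 5000L)
  oracle <- vapply(seq_len(200), function(b) {
    mean(((b - 1L) * 50L):(b * 50L - 1L))
  }, numeric(1))
  expect_equal(unname(bins), oracle)
  # mean preservation: bins times bin width recover the total signal
  expect_equal(sum(bins) * 50, sum(ramp$value))
})

test_that("minus-strand genes are orientation-normalized", {
  set.seed(11)
  vals <- rgamma(10000, 2, 2)
  plus <- data.frame(chrom = "chr1", start = 0:9999, end = 1:10000,
                     value = vals)
  minus <- data.frame(chrom = "chr1", start = 0:9999, end = 1:10000,
                      value = rev(vals))
  b_plus <- bin_signal(plus, "chr1", tss = 5000L, strand = "+")
  b_minus <- bin_signal(minus, "chr1", tss = 5000L, strand = "-")
  expect_equal(unname(b_plus), unname(b_minus))
})

test_that("binning pads a truncated window with zeros and rejects bad input", {
  track <- data.frame(chrom = "chr1", start = 0L, end = 20000L, value = 1.0)
  expect_warning(bins <- bin_signal(track, "chr1", tss = 1000L),
                 "chromosome start")
  # first 4000 bp of the window precede the chromosome: 80 zero bins
  expect_true(all(bins[1:80] == 0))
  expect_true(all(bins[81:200] == 1))

  neg <- data.frame(chrom = "chr1", start = 0L, end = 20000L, value = -1.0)
  expect_error(bin_signal(neg, "chr1", tss = 10000L), "negative")
  expect_error(bin_signal(track, "chr1", tss = 10000L, flank_bp = 5000L,
                          bin_bp = 33L), "divisible")
})

test_that("expression binarization splits at the median with balanced ties", {
  expect_identical(unname(binarize_expression(c(1, 2, 3, 4))),
                   c(0L, 0L, 1L, 1L))
  expect_identical(unname(binarize_expression(c(0, 0, 5, 9))),
                   c(0L, 0L, 1L, 1L))
  lab <- binarize_expression(c(3, 3, 3, 7))
  expect_identical(sum(lab), 2L)
  expect_error(binarize_expression(c(2, 2, 2)), "identical")
  expect_error(binarize_expression(5), "at least 2")

  # balance and median-rule properties over random vectors with ties
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:200, 1)
    v <- round(rgamma(n, 1, 1), sample(0:2, 1))
    if (length(unique(v)) == 1L) next
    lab <- binarize_expression(v)
    expect_lte(abs(sum(lab == 1L) - sum(lab == 0L)), 1L)
    expect_true(all(lab[v > stats::median(v)] == 1L))
    expect_true(all(lab[v < stats::median(v)] == 0L))
  }
})

test_that("gene splits have the documented sizes and are reproducible", {
  ids <- paste0("g", seq_len(18421))
  sp <- split_genes(ids, n_train = 6600, seed = 3)
  expect_identical(lengths(sp[c("train", "valid", "test")]),
                   c(train = 6600L, valid = 5911L, test = 5910L))
  expect_length(intersect(sp$train, sp$valid), 0L)
  expect_length(intersect(sp$valid, sp$test), 0L)
  expect_setequal(c(sp$train, sp$valid, sp$test), ids)

  sp10 <- split_genes(paste0("g", 1:10), n_train = 6, seed = 1)
  expect_identical(lengths(sp10[c("train", "valid", "test")]),
                   c(train = 6L, valid = 2L, test = 2L))
  sp11 <- split_genes(paste0("g", 1:11), n_train = 6, seed = 1)
  expect_identical(lengths(sp11[c("train", "valid", "test")]),
                   c(train = 6L, valid = 3L, test = 2L))

  expect_identical(split_genes(ids, 6600, seed = 9),
                   split_genes(ids, 6600, seed = 9))
  expect_false(identical(split_genes(ids, 6600, seed = 1)$train,
                         split_genes(ids, 6600, seed = 2)$train))
  expect_error(split_genes(ids, n_train = 6601, seed = 1), "even")
})

test_that("annotation, expression, profile and split files round-trip", {
  tmp <- withr::local_tempdir()

  bed <- file.path(tmp, "genes.bed")
  writeLines(c("chr1\t100\t500\tgeneA\t0\t+",
               "chr2\t900\t1500\tgeneB\t0\t-"), bed)
  ann <- read_gene_annotation(bed)
  expect_identical(ann$tss, c(100L, 1499L))
  expect_identical(ann$strand, c("+", "-"))

  tsv <- file.path(tmp, "genes.tsv")
  writeLines(c("gene_id\tchrom\ttss\tstrand", "geneA\tchr1\t101\t+"), tsv)
  expect_identical(read_gene_annotation(tsv, one_based = TRUE)$tss, 100L)

  expr_f <- file.path(tmp, "expr.tsv")
  writeLines(c("gene_id\tvalue", "geneA\t3.5", "geneB\t0"), expr_f)
  ev <- read_expression_table(expr_f)
  expect_identical(unname(ev), c(3.5, 0))

  ds <- tiny_dataset()
  pf <- file.path(tmp, "profiles.tsv")
  write_profiles(ds$profiles, pf)
  back <- read_profiles(pf)
  expect_equal(unclass(back), unclass(ds$profiles), tolerance = 1e-12)

  sp <- split_genes(names(ds$labels), n_train = 100, seed = 4)
  sf <- file.path(tmp, "split.tsv")
  write_split(sp, sf)
  sp2 <- read_split(sf)
  expect_identical(sp2$train, sp$train)
  expect_identical(sp2$seed, sp$seed)
})
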