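#' Configuration of the synthetic ChIP-seq profile generator
#'
#' The generator emulates the statistical structure the classifier
#' assumes: per gene, five non-negative binned signal tracks of 200 bins
#' with gamma-distributed background, a short motif planted additively at
#' random positions of an upstream promoter window - more often in
#' "high-expression" genes - and a right-skewed expression value whose
#' median split defines the labels.  Planting amplitudes are jittered so
#' motif occurrences differ in scale but not in shape, exercising the
#' scale invariance of correlation matching.
#'
#' @param n_genes number of genes (an even count keeps classes exactly
#'   balanced).
#' @param n_bins bins per profile row (default 200).
#' @param marks histone-mark names (their number sets the track count).
#' @param motif_shape template vector in \[0, 1\] planted into profiles.
#' @param motif_mark index of the mark carrying the motif.
#' @param placement signed bin range (inclusive) that planted motifs must
#'   fall inside, default bins -80 to -15, an upstream promoter window
#'   wide enough that a Poisson(5) number of non-overlapping copies
#'   essentially always fits.
#' @param lambda_high,lambda_low Poisson means of the per-gene planted
#'   copy number in high- and low-expression genes.
#' @param background_shape,background_scale gamma parameters of the
#'   background signal per bin.
#' @param amplitude length-2 range of the uniform planting amplitude.
#' @param meanlog_low,meanlog_high,sdlog log-normal expression parameters
#'   per class.
#' @param seed integer seed; generation is fully deterministic.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L, n_bins = 200L,
                       marks = default_marks(),
                       motif_shape = c(0.05, 0.95, 0.05, 0.9, 0.1, 0.85),
                       motif_mark = 1L, placement = c(-80L, -15L),
                       lambda_high = 5, lambda_low = 1,
                       background_shape = 2, background_scale = 0.5,
                       amplitude = c(6, 12),
                       meanlog_low = 0, meanlog_high = 4, sdlog = 0.5,
                       seed = 1L) {
  if (lambda_high == lambda_low) {
    message("lambda_high == lambda_low: generating a null dataset ",
            "with no class signal")
  }
  if (stats::sd(motif_shape) == 0) stop("motif shape must not be constant")
  L <- length(motif_shape)
  idx <- bin_index(placement, n_bins)
  if (idx[2L] - idx[1L] + 1L < L) {
    stop("placement range is narrower than the motif")
  }
  structure(list(n_genes = as.integer(n_genes), n_bins = as.integer(n_bins),
                 marks = marks, motif_shape = motif_shape,
                 motif_mark = as.integer(motif_mark),
                 placement = as.integer(placement),
                 lambda_high = lambda_high, lambda_low = lambda_low,
                 background_shape = background_shape,
                 background_scale = background_scale,
                 amplitude = amplitude, meanlog_low = meanlog_low,
                 meanlog_high = meanlog_high, sdlog = sdlog,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic dataset with planted motifs
#'
#' @param config a [sim_config()].
#' @return an `hm_dataset` list: `profiles` (`hm_profiles`), `expression`
#'   (named vector), `labels` (0/1, from the median split), `intended`
#'   (the class each gene was generated as), `ledger` (one row per
#'   planted occurrence: gene, mark, start bin, amplitude) and `config`.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    G <- config$n_genes
    M <- length(config$marks)
    B <- config$n_bins
    L <- length(config$motif_shape)
    gene_ids <- sprintf("gene_%04d", seq_len(G))
    arr <- array(
      stats::rgamma(G * M * B, shape = config$background_shape,
                    scale = config$background_scale),
      dim = c(G, M, B),
      dimnames = list(gene_ids, config$marks, bin_labels(B))
    )
    n_high <- G %/% 2L
    intended <- sample(rep(c(1L, 0L), c(n_high, G - n_high)))

    place_idx <- bin_index(config$placement, B)
    allowed <- seq.int(place_idx[1L], place_idx[2L] - L + 1L)
    max_fit <- length(allowed) %/% L + 1L
    ledger <- list()
    for (g in seq_len(G)) {
      lambda <- if (intended[g] == 1L) config$lambda_high else config$lambda_low
      n_plant <- min(stats::rpois(1L, lambda), max_fit)
      if (n_plant == 0L) next
      # greedy non-overlapping placement within the allowed window
      starts <- integer(0)
      for (cand in sample(allowed)) {
        if (length(starts) == n_plant) break
        if (all(abs(cand - starts) >= L)) starts <- c(starts, cand)
      }
      for (st in starts) {
        a <- stats::runif(1L, config$amplitude[1L], config$amplitude[2L])
        span <- st:(st + L - 1L)
        arr[g, config$motif_mark, span] <-
          arr[g, config$motif_mark, span] + a * config$motif_shape
        ledger[[length(ledger) + 1L]] <- data.frame(
          gene_id = gene_ids[g], mark = config$motif_mark, start = st,
          amplitude = a, intended = intended[g]
        )
      }
    }
    ledger <- if (length(ledger)) do.call(rbind, ledger) else
      data.frame(gene_id = character(0), mark = integer(0),
                 start = integer(0), amplitude = numeric(0),
                 intended = integer(0))

    meanlog <- ifelse(intended == 1L, config$meanlog_high, config$meanlog_low)
    expr <- stats::rlnorm(G, meanlog = meanlog, sdlog = config$sdlog)
    names(expr) <- gene_ids
    labels <- binarize_expression(expr)

    structure(list(profiles = hm_profiles(arr), expression = expr,
                   labels = labels, intended = intended, ledger = ledger,
                   config = config),
              class = "hm_dataset")
  })
}

#' @export
print.hm_dataset <- function(x, ...) {
  cat("<hm_dataset> ", x$config$n_genes, " genes, ",
      length(x$config$marks), " marks, ", nrow(x$ledger),
      " planted motif occurrences (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

# Deterministic random motif shape rescaled to span [0, 1].
random_motif_shape <- function(L, seed) {
  withr::with_seed(seed, {
    u <- stats::runif(L)
    (u - min(u)) / (max(u) - min(u))
  })
}

#' Generate several samples sharing (or not) the planted motif
#'
#' Emulates the multi-sample setting used to study pattern transfer: with
#' `shared_motif = TRUE` every sample plants the same motif into
#' independent background noise; with `FALSE` each sample draws its own
#' motif shape, so a model trained on one sample should transfer no
#' signal to another.
#'
#' @param config base [sim_config()].
#' @param n_samples number of samples (>= 2).
#' @param shared_motif logical.
#' @return list of `hm_dataset`s.
#' @export
make_paired_samples <- function(config = sim_config(), n_samples = 2L,
                                shared_motif = TRUE) {
  if (n_samples < 2L) stop("n_samples must be >= 2")
  lapply(seq_len(n_samples), function(s) {
    cfg <- config
    cfg$seed <- config$seed + 7919L * s
    if (!shared_motif && s > 1L) {
      cfg$motif_shape <- random_motif_shape(length(config$motif_shape),
                                            config$seed + 31L * s)
    }
    class(cfg) <- "sim_config"
    generate_dataset(cfg)
  })
}

#' How well a pattern recovers a planted motif
#'
#' A detector can fire at a fixed lag of the planted template (for an
#' alternating motif a one-bin shift flips the phase), so shape recovery
#' is measured as the maximum Pearson correlation between the pattern's
#' shape and any equal-length window of the motif padded on both sides
#' with its own minimum (the flat-background level in shape space).
#'
#' @param pattern an `hm_pattern` (or a bare shape vector).
#' @param motif_shape the planted template.
#' @return maximum correlation over all lags, in \[-1, 1\].
#' @export
pattern_recovery <- function(pattern, motif_shape) {
  shape <- if (inherits(pattern, "hm_pattern")) pattern$shape else
    as.numeric(pattern)
  L <- length(shape)
  pad <- rep(min(motif_shape), L - 1L)
  padded <- c(pad, motif_shape, pad)
  best <- -1
  for (o in seq_len(length(padded) - L + 1L)) {
    win <- padded[o:(o + L - 1L)]
    if (stats::sd(win) == 0) next
    best <- max(best, stats::cor(shape, win))
  }
  best
}
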