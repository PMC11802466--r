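#' Search box for the pattern-encoding particle
#'
#' A candidate pattern is encoded as an 11-dimensional real vector:
#' coordinate 1 selects the histone mark, coordinate 2 the shape length L
#' (2 to 8), coordinate 3 the correlation cutoff (0.5 to 0.99) and
#' coordinates 4 to 11 the shape values in \[0, 1\] (only the first L are
#' used).  Discrete coordinates are decoded by flooring over equispaced
#' cells, so every value, including the endpoints, owns an equal slice of
#' its interval.
#'
#' @param n_marks number of histone marks (default 5).
#' @param max_len maximum shape length (default 8).
#' @return list with `lower` and `upper` bound vectors (length 11).
#' @export
particle_bounds <- function(n_marks = 5L, max_len = 8L) {
  list(lower = c(1, 2, 0.5, rep(0, max_len)),
       upper = c(n_marks + 1, max_len + 1, 0.99, rep(1, max_len)))
}

# floor-decode a continuous coordinate onto integers lo..hi given the cell
# convention of particle_bounds (coordinate ranges over [lo, hi + 1]).
decode_int <- function(x, lo, hi) {
  as.integer(max(lo, min(hi, floor(x))))
}

#' Decode a particle position into a pattern
#'
#' Total on the search box: every position decodes to a valid pattern.  In
#' the measure-zero case where the first L shape coordinates are identical
#' (a constant shape has no defined correlation) the last shape value is
#' shifted by 0.5 towards the opposite end of \[0, 1\].
#'
#' @param x numeric vector of length 11 within [particle_bounds()].
#' @param marks optional character vector of mark names for reporting.
#' @return an `hm_pattern`.
#' @export
decode_particle <- function(x, marks = NULL) {
  n_marks <- if (is.null(marks)) 5L else length(marks)
  mark <- decode_int(x[1L], 1L, n_marks)
  len <- decode_int(x[2L], 2L, length(x) - 3L)
  cutoff <- min(max(x[3L], 0.5), 0.99)
  shape <- x[3L + seq_len(len)]
  shape <- pmin(pmax(shape, 0), 1)
  if (stats::sd(shape) == 0) {
    shape[len] <- shape[len] + if (shape[len] <= 0.5) 0.5 else -0.5
  }
  hm_pattern(mark, shape, cutoff,
             mark_name = if (!is.null(marks)) marks[mark])
}

#' Configuration of the pattern-extraction loop
#'
#' @param auc_target stop once the accepted training AUC reaches this
#'   (default 0.999).
#' @param max_rounds ceiling on extraction rounds.
#' @param max_stagnant_rounds stop after this many consecutive rounds whose
#'   best candidate fails to improve the accepted AUC.
#' @param subset_size genes scored per round (stratified; default 3000,
#'   capped at the training-set size).
#' @param booster list with `nrounds` and `eta` for the scoring classifier
#'   (defaults 50 and 0.2).
#' @param pso a [pso_control()] for the per-round swarm search.
#' @param seed master seed; per-round subset and swarm seeds are derived
#'   from it by fixed offsets.
#' @return an `extraction_config` list.
#' @export
extraction_config <- function(auc_target = 0.999, max_rounds = 20L,
                              max_stagnant_rounds = 3L, subset_size = 3000L,
                              booster = list(nrounds = 50L, eta = 0.2),
                              pso = pso_control(max_iter = 25L,
                                                max_stagnant = 8L),
                              seed = 1L) {
  structure(list(auc_target = auc_target, max_rounds = as.integer(max_rounds),
                 max_stagnant_rounds = as.integer(max_stagnant_rounds),
                 subset_size = as.integer(subset_size), booster = booster,
                 pso = pso, seed = as.integer(seed)),
            class = "extraction_config")
}

#' Score a candidate pattern by subset training AUC
#'
#' Counts the candidate's matches on the evaluation genes, appends the
#' column to the already-accepted feature columns, trains the scoring
#' booster (50 rounds, shrinkage 0.2 by default) on those genes and
#' returns the training AUC on the same genes.  The existing feature
#' matrix is never mutated.
#'
#' @param pattern candidate `hm_pattern`.
#' @param profiles an `hm_profiles` object (the evaluation genes).
#' @param labels 0/1 labels for those genes.
#' @param feature_matrix previously accepted feature columns for the same
#'   genes (0-column matrix when no pattern is accepted yet).
#' @param booster list with `nrounds`, `eta`.
#' @param seed booster seed.
#' @return AUC in \[0, 1\].
#' @export
score_candidate <- function(pattern, profiles, labels,
                            feature_matrix = NULL,
                            booster = list(nrounds = 50L, eta = 0.2),
                            seed = 1L) {
  P <- mark_matrix(profiles, pattern$mark)
  if (is.null(feature_matrix)) {
    feature_matrix <- matrix(0L, nrow = nrow(P), ncol = 0L)
  }
  cand <- count_matrix_for_pattern(P, pattern)
  score_counts(cand, feature_matrix, labels, booster, seed)
}

# Fast path shared with the extraction loop: candidate counts already
# computed.
score_counts <- function(cand, feature_matrix, labels, booster, seed) {
  X <- cbind(feature_matrix, candidate = cand)
  if (all(apply(X, 2L, function(col) length(unique(col)) == 1L))) {
    return(0.5)  # no informative feature at all: chance-level by definition
  }
  m <- fit_booster(X, labels, nrounds = booster$nrounds, eta = booster$eta,
                   seed = seed)
  auc(booster_scores(m, X), labels)
}

# Balanced (stratified) subset of gene indices.
stratified_subset <- function(labels, size, seed) {
  size <- min(size, length(labels))
  withr::with_seed(seed, {
    pos <- which(labels == 1L)
    neg <- which(labels == 0L)
    n_pos <- min(length(pos), ceiling(size / 2))
    n_neg <- min(length(neg), size - n_pos)
    sort(c(sample(pos, n_pos), sample(neg, n_neg)))
  })
}

#' Extract predictive patterns by swarm search
#'
#' The core loop: each round draws a fresh stratified evaluation subset of
#' the training genes, runs an SPSO2007 swarm over the 11-dimensional
#' pattern encoding with objective "negative subset training AUC given the
#' already-accepted features", and accepts the round's best pattern only
#' if it strictly improves the best accepted AUC.  The loop stops when the
#' accepted AUC reaches `auc_target`, after `max_stagnant_rounds` rounds
#' without improvement, or at `max_rounds`.
#'
#' @param profiles `hm_profiles` for the training genes.
#' @param labels 0/1 training labels (balanced).
#' @param config an [extraction_config()].
#' @return an `hm_extraction` list: `patterns` (accepted, in order),
#'   `feature_matrix` (full training set), `trace` (one row per round) and
#'   `best_auc`.
#' @export
extract_features <- function(profiles, labels, config = extraction_config()) {
  stopifnot(inherits(profiles, "hm_profiles"))
  if (length(labels) != dim(profiles)[1L]) {
    stop("labels and profiles disagree in gene count")
  }
  if (length(unique(labels)) < 2L) stop("need both classes in training labels")
  marks <- dimnames(profiles)[[2L]]
  bounds <- particle_bounds(n_marks = length(marks))
  n_genes <- dim(profiles)[1L]

  patterns <- list()
  fm_full <- matrix(0L, nrow = n_genes, ncol = 0L,
                    dimnames = list(dimnames(profiles)[[1L]], NULL))
  best_auc <- 0.5
  stagnant <- 0L
  trace <- list()

  for (round in seq_len(config$max_rounds)) {
    subset_seed <- config$seed + 1009L * round
    swarm_seed <- config$seed + 1009L * round + 500009L
    idx <- stratified_subset(labels, config$subset_size, subset_seed)
    lab_sub <- labels[idx]
    mark_sub <- lapply(seq_along(marks), function(m) {
      mark_matrix(profiles, m)[idx, , drop = FALSE]
    })
    fm_sub <- fm_full[idx, , drop = FALSE]

    objective <- function(x) {
      p <- decode_particle(x, marks = marks)
      cand <- count_matrix_for_pattern(mark_sub[[p$mark]], p)
      -score_counts(cand, fm_sub, lab_sub, config$booster, config$seed)
    }
    ctl <- config$pso
    ctl$seed <- swarm_seed
    ctl$value_to_reach <- -config$auc_target
    res <- pso_minimize(objective, bounds$lower, bounds$upper, ctl)
    cand_pattern <- decode_particle(res$par, marks = marks)
    cand_auc <- -res$value

    accepted <- cand_auc > best_auc
    if (accepted) {
      patterns[[length(patterns) + 1L]] <- cand_pattern
      P_full <- mark_matrix(profiles, cand_pattern$mark)
      fm_full <- cbind(fm_full, count_matrix_for_pattern(P_full, cand_pattern))
      colnames(fm_full) <- paste0("pattern_", seq_len(ncol(fm_full)))
      best_auc <- cand_auc
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
    }
    trace[[round]] <- data.frame(
      round = round, candidate_auc = cand_auc, accepted = accepted,
      best_auc = best_auc, mark = cand_pattern$mark,
      length = length(cand_pattern$shape), cutoff = cand_pattern$cutoff,
      evals = res$evals
    )
    if (best_auc >= config$auc_target) break
    if (stagnant >= config$max_stagnant_rounds) break
  }
  if (length(patterns) == 0L) {
    warning("no pattern accepted within the stagnation budget; ",
            "returning an empty feature set")
  }
  structure(list(patterns = patterns, feature_matrix = fm_full,
                 trace = do.call(rbind, trace), best_auc = best_auc,
                 config = config),
            class = "hm_extraction")
}

#' @export
print.hm_extraction <- function(x, ...) {
  cat("<hm_extraction> ", length(x$patterns), " accepted patterns, ",
      "best training AUC ", format(x$best_auc, digits = 4), "\n", sep = "")
  invisible(x)
}
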