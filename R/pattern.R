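#' Histone-modification pattern
#'
#' A pattern is a short shape template over consecutive bins of one histone
#' mark together with a correlation cutoff.  A window of a binned profile
#' "matches" the pattern when its Pearson correlation with the shape is
#' strictly above the cutoff; the per-gene match count is the classifier
#' feature.  Because Pearson correlation is invariant under positive affine
#' transforms of the window, matching depends only on the signal's shape,
#' not its scale.
#'
#' @param mark histone-mark index (1-based) into the profile's mark set.
#' @param shape numeric vector of length 2 to 8, values in \[0, 1\], not
#'   constant.
#' @param cutoff correlation threshold in \[0.5, 0.99\].
#' @param mark_name optional mark name carried along for reporting.
#' @return an object of class `hm_pattern`.
#' @examples
#' p <- hm_pattern(1, c(0.2, 0.8, 0.2), 0.9)
#' match_count(c(rep(0.1, 10), 0.2, 0.8, 0.2, rep(0.1, 10)), p)
#' @export
hm_pattern <- function(mark, shape, cutoff, mark_name = NULL) {
  mark <- as.integer(mark)
  shape <- as.numeric(shape)
  if (length(shape) < 2L || length(shape) > 8L) {
    stop("shape length must be in [2, 8]")
  }
  if (any(shape < 0 | shape > 1)) stop("shape values must lie in [0, 1]")
  if (stats::sd(shape) == 0) stop("shape must not be constant")
  if (cutoff < 0.5 || cutoff > 0.99) stop("cutoff must lie in [0.5, 0.99]")
  if (mark < 1L) stop("mark index must be >= 1")
  structure(list(mark = mark, shape = shape, cutoff = as.numeric(cutoff),
                 mark_name = mark_name),
            class = "hm_pattern")
}

#' @export
print.hm_pattern <- function(x, ...) {
  cat("<hm_pattern> mark ", x$mark,
      if (!is.null(x$mark_name)) paste0(" (", x$mark_name, ")"),
      ", L = ", length(x$shape), ", cutoff = ", format(x$cutoff, digits = 3),
      "\n  shape: ", paste(format(x$shape, digits = 2), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Sliding-window correlations of profile rows with a shape
#'
#' @param x numeric vector (one profile row) or matrix (genes x bins).
#' @param shape the template vector.
#' @return matrix of Pearson correlations, one column per window start
#'   (`NA` where the window has zero variance).
#' @export
window_correlations <- function(x, shape) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  window_corr_cpp(x, as.numeric(shape))
}

#' Count pattern matches in one profile row
#'
#' Number of window start positions whose Pearson correlation with the
#' pattern shape is strictly above the pattern cutoff.  Zero-variance
#' (flat) windows never match; overlapping matches each count.
#'
#' @param profile_row numeric vector of binned signal for the pattern's
#'   mark (length >= pattern length).
#' @param pattern an `hm_pattern`.
#' @return non-negative integer.
#' @export
match_count <- function(profile_row, pattern) {
  stopifnot(inherits(pattern, "hm_pattern"))
  window_match_count_cpp(matrix(as.numeric(profile_row), nrow = 1L),
                         pattern$shape, pattern$cutoff)[1L]
}

#' Window start positions where a pattern matches
#'
#' @inheritParams match_count
#' @return integer vector of matching window start indices (1-based into
#'   the profile row).
#' @export
match_positions <- function(profile_row, pattern) {
  stopifnot(inherits(pattern, "hm_pattern"))
  r <- window_correlations(as.numeric(profile_row), pattern$shape)[1L, ]
  which(!is.na(r) & r > pattern$cutoff)
}

# Vectorized match counts for all genes of one mark matrix.
count_matrix_for_pattern <- function(P, pattern) {
  window_match_count_cpp(P, pattern$shape, pattern$cutoff)
}

#' Build the genes x patterns feature matrix
#'
#' Entry (g, k) is the match count of pattern k in gene g's profile row for
#' that pattern's mark.  Columns are ordered by pattern acceptance order and
#' named `pattern_1`, `pattern_2`, ...
#'
#' @param profiles an `hm_profiles` object.
#' @param patterns list of `hm_pattern` objects (may be empty).
#' @return integer matrix, genes x patterns.
#' @export
build_feature_matrix <- function(profiles, patterns) {
  stopifnot(inherits(profiles, "hm_profiles"))
  genes <- dimnames(profiles)[[1L]]
  fm <- matrix(0L, nrow = length(genes), ncol = length(patterns),
               dimnames = list(genes,
                               if (length(patterns))
                                 paste0("pattern_", seq_along(patterns))))
  for (k in seq_along(patterns)) {
    P <- mark_matrix(profiles, patterns[[k]]$mark)
    fm[, k] <- count_matrix_for_pattern(P, patterns[[k]])
  }
  fm
}

#' Serialize / deserialize patterns as JSON
#'
#' Records `{mark, mark_name, shape, cutoff}` in acceptance order.
#'
#' @param patterns list of `hm_pattern` objects.
#' @param path file path.
#' @return `patterns_from_json()` returns a list of `hm_pattern` objects.
#' @export
patterns_to_json <- function(patterns, path) {
  recs <- lapply(patterns, function(p) {
    list(mark = p$mark, mark_name = p$mark_name, shape = p$shape,
         cutoff = p$cutoff)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname patterns_to_json
#' @export
patterns_from_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    hm_pattern(r$mark, unlist(r$shape), r$cutoff,
               mark_name = r$mark_name %||% NULL)
  })
}
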