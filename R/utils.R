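`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert between signed bin labels and array column indices
#'
#' Binned profiles span TSS - flank to TSS + flank and are labelled with
#' signed bin indices -n/2 ... -1, +1 ... +n/2 (no bin 0): bin -1 is the
#' 50-bp window immediately upstream of the TSS in transcription
#' orientation, bin +1 immediately downstream.  Internally the bins of a
#' profile row are stored in columns 1 ... n; these helpers convert between
#' the two conventions.
#'
#' @param bin integer vector of signed bin labels (no zero allowed).
#' @param index integer vector of column indices in 1 ... n_bins.
#' @param n_bins total number of bins per profile row (default 200).
#' @return `bin_index()` returns column indices; `signed_bin()` returns
#'   signed labels.
#' @examples
#' bin_index(c(-100, -1, 1, 100))
#' signed_bin(c(1, 100, 101, 200))
#' @export
bin_index <- function(bin, n_bins = 200L) {
  bin <- as.integer(bin)
  if (any(bin == 0L)) stop("there is no bin 0; bins are -n/2...-1, +1...+n/2")
  half <- n_bins %/% 2L
  if (any(abs(bin) > half)) stop("bin label out of range for ", n_bins, " bins")
  ifelse(bin < 0L, bin + half + 1L, bin + half)
}

#' @rdname bin_index
#' @export
signed_bin <- function(index, n_bins = 200L) {
  index <- as.integer(index)
  if (any(index < 1L | index > n_bins)) stop("bin index out of 1...", n_bins)
  half <- n_bins %/% 2L
  ifelse(index <= half, index - half - 1L, index - half)
}

#' Fraction of the profile covered by a signed bin span
#'
#' Convenience for statements like "bins -64 to -32 cover 16.5% of the
#' input region": counts the bins of the span (inclusive, skipping the
#' non-existent bin 0) and divides by the total bin count.
#'
#' @param from,to signed bin labels bounding the span (inclusive).
#' @param n_bins total number of bins (default 200).
#' @return fraction in (0, 1].
#' @examples
#' bin_span_fraction(-64, -32)  # 33 bins / 200 = 0.165
#' @export
bin_span_fraction <- function(from, to, n_bins = 200L) {
  if (from > to) stop("`from` must be <= `to`")
  span <- setdiff(seq.int(from, to), 0L)
  length(span) / n_bins
}

# Default histone marks, in the conventional order used throughout.
default_marks <- function() {
  c("H3K4me3", "H3K4me1", "H3K36me3", "H3K9me3", "H3K27me3")
}

bin_labels <- function(n_bins = 200L) {
  half <- n_bins %/% 2L
  paste0("bin_", c(seq.int(-half, -1L), seq.int(1L, half)))
}
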