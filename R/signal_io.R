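#' Read a gene annotation (TSS coordinates and strands)
#'
#' Accepts either BED6 (0-based half-open; the TSS is `start` for `+` genes
#' and `end - 1` for `-` genes) or a headered TSV with columns `gene_id`,
#' `chrom`, `tss`, `strand`.  TSV coordinates are 0-based unless
#' `one_based = TRUE`.
#'
#' @param path file path.
#' @param format `"auto"` (sniff header), `"bed"` or `"tsv"`.
#' @param one_based set `TRUE` when a TSV uses 1-based coordinates.
#' @return data.frame with columns `gene_id`, `chrom`, `tss` (0-based),
#'   `strand`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "tsv"),
                                 one_based = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("gene_id", first, fixed = TRUE)) "tsv" else "bed"
  }
  if (format == "bed") {
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    if (ncol(dt) < 6L) stop("BED annotation needs 6 columns (strand required)")
    ann <- data.frame(
      gene_id = as.character(dt[[4L]]),
      chrom   = as.character(dt[[1L]]),
      tss     = as.integer(ifelse(dt[[6L]] == "+", dt[[2L]], dt[[3L]] - 1L)),
      strand  = as.character(dt[[6L]]),
      stringsAsFactors = FALSE
    )
  } else {
    dt <- data.table::fread(path, header = TRUE, sep = "\t")
    need <- c("gene_id", "chrom", "tss", "strand")
    if (!all(need %in% names(dt))) {
      stop("TSV annotation needs columns: ", paste(need, collapse = ", "))
    }
    ann <- as.data.frame(dt[, need, with = FALSE])
    ann$gene_id <- as.character(ann$gene_id)
    ann$chrom <- as.character(ann$chrom)
    ann$tss <- as.integer(ann$tss)
    if (one_based) ann$tss <- ann$tss - 1L
  }
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene_id in annotation")
  if (any(ann$tss < 0)) stop("negative TSS coordinate")
  if (!all(ann$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  invisible(ann)
}

#' Read a bedGraph signal track
#'
#' 4 columns (chrom, start, end, value), 0-based half-open, no header.
#' Track lines and comments are skipped.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          skip = "chr", fill = TRUE)
  dt <- dt[!is.na(dt$start) & !is.na(dt$value), ]
  as.data.frame(dt)
}

#' Read a two-column expression table
#'
#' @param path TSV with columns `gene_id` and `value` (header optional; the
#'   first two columns are used).
#' @return named numeric vector of expression values.
#' @export
read_expression_table <- function(path) {
  dt <- data.table::fread(path, header = "auto", sep = "\t")
  vals <- as.numeric(dt[[2L]])
  names(vals) <- as.character(dt[[1L]])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("expression values must be finite and non-negative")
  }
  vals
}

#' Bin a signal track around one TSS
#'
#' Extracts the window TSS - flank_bp ... TSS + flank_bp (0-based half-open)
#' from an interval track, averages the per-base signal within consecutive
#' `bin_bp` windows and orients the result so that the first bin is always
#' the 5'-most (upstream in transcription orientation): for minus-strand
#' genes the bin order is reversed.  Bases not covered by the track read
#' as 0, the bedGraph convention for absent signal.
#'
#' @param track data.frame with columns `chrom`, `start`, `end`, `value`
#'   (a `chrom` column is optional when the track holds one chromosome).
#' @param chrom,tss,strand gene coordinates (0-based TSS) and strand.
#' @param flank_bp half-width of the window (default 5000).
#' @param bin_bp bin width in bp (default 50); must divide `flank_bp`.
#' @return numeric vector of `2 * flank_bp / bin_bp` bin means, named with
#'   signed bin labels.
#' @export
bin_signal <- function(track, chrom, tss, strand = "+",
                       flank_bp = 5000L, bin_bp = 50L) {
  if (flank_bp %% bin_bp != 0L) stop("flank_bp must be divisible by bin_bp")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  win0 <- tss - flank_bp
  win1 <- tss + flank_bp
  if (win0 < 0) {
    warning("window extends past chromosome start; missing bases read as 0")
  }
  if ("chrom" %in% names(track)) track <- track[track$chrom == chrom, , drop = FALSE]
  keep <- track$end > max(win0, 0L) & track$start < win1
  track <- track[keep, , drop = FALSE]
  if (nrow(track) && any(track$value < 0)) stop("negative signal values in track")
  width <- 2L * flank_bp
  base <- numeric(width)
  for (i in seq_len(nrow(track))) {
    s <- max(track$start[i], win0)
    e <- min(track$end[i], win1)
    if (e > s) base[(s - win0 + 1L):(e - win0)] <- track$value[i]
  }
  bins <- colMeans(matrix(base, nrow = bin_bp))
  if (strand == "-") bins <- rev(bins)
  names(bins) <- bin_labels(width %/% bin_bp)
  bins
}

#' Build binned profiles for a gene set over several histone marks
#'
#' @param tracks named list of signal tracks (one per histone mark; see
#'   [bin_signal()] for the format).  The list names become the mark names.
#' @param annotation data.frame as returned by [read_gene_annotation()].
#' @param flank_bp,bin_bp window geometry, see [bin_signal()].
#' @return an `hm_profiles` object: a 3-d array gene x mark x bin.
#' @export
bin_profiles <- function(tracks, annotation, flank_bp = 5000L, bin_bp = 50L) {
  validate_annotation(annotation)
  marks <- names(tracks)
  if (is.null(marks) || any(marks == "")) stop("`tracks` must be a named list")
  n_bins <- 2L * flank_bp %/% bin_bp
  arr <- array(
    0, dim = c(nrow(annotation), length(marks), n_bins),
    dimnames = list(annotation$gene_id, marks, bin_labels(n_bins))
  )
  for (m in seq_along(marks)) {
    for (g in seq_len(nrow(annotation))) {
      arr[g, m, ] <- bin_signal(tracks[[m]], annotation$chrom[g],
                                annotation$tss[g], annotation$strand[g],
                                flank_bp, bin_bp)
    }
  }
  hm_profiles(arr)
}

#' Binned-profile container
#'
#' Wraps a gene x mark x bin array of non-negative binned ChIP-seq signal.
#'
#' @param arr 3-d numeric array with dimnames (gene ids, mark names, bin
#'   labels).
#' @return an object of class `hm_profiles`.
#' @export
hm_profiles <- function(arr) {
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  if (is.null(dimnames(arr)[[1L]]) || is.null(dimnames(arr)[[2L]])) {
    stop("profiles need gene and mark dimnames")
  }
  if (any(!is.finite(arr)) || any(arr < 0)) {
    stop("profile values must be finite and non-negative")
  }
  structure(arr, class = c("hm_profiles", "array"))
}

#' @export
print.hm_profiles <- function(x, ...) {
  d <- dim(x)
  cat("<hm_profiles> ", d[1L], " genes x ", d[2L], " marks x ", d[3L],
      " bins\n", sep = "")
  cat("marks:", paste(dimnames(x)[[2L]], collapse = ", "), "\n")
  invisible(x)
}

#' Extract one mark's gene-by-bin matrix from a profile set
#'
#' @param profiles an `hm_profiles` object.
#' @param mark mark name or index.
#' @return numeric matrix, genes x bins.
#' @export
mark_matrix <- function(profiles, mark) {
  marks <- dimnames(profiles)[[2L]]
  if (is.character(mark)) {
    idx <- match(mark, marks)
    if (is.na(idx)) stop("mark '", mark, "' not present in profiles")
  } else {
    idx <- as.integer(mark)
    if (idx < 1L || idx > length(marks)) {
      stop("mark index ", idx, " not present in profiles (",
           length(marks), " marks)")
    }
  }
  m <- unclass(profiles)[, idx, , drop = FALSE]
  dim(m) <- dim(profiles)[c(1L, 3L)]
  dimnames(m) <- dimnames(profiles)[c(1L, 3L)]
  m
}

#' Write / read a binned-profile archive
#'
#' Long-format delimited table: `gene_id`, `mark`, then one column per bin
#' (`bin_-100` ... `bin_+100`).
#'
#' @param profiles an `hm_profiles` object.
#' @param path output/input file path (TSV; `.gz` allowed).
#' @return `read_profiles()` returns an `hm_profiles` object.
#' @export
write_profiles <- function(profiles, path) {
  d <- dim(profiles)
  genes <- dimnames(profiles)[[1L]]
  marks <- dimnames(profiles)[[2L]]
  rows <- vector("list", d[2L])
  for (m in seq_len(d[2L])) {
    mat <- mark_matrix(profiles, m)
    rows[[m]] <- data.table::data.table(
      gene_id = genes, mark = marks[m], data.table::as.data.table(mat)
    )
  }
  out <- data.table::rbindlist(rows)
  data.table::setnames(out, c("gene_id", "mark", dimnames(profiles)[[3L]]))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  genes <- unique(dt$gene_id)
  marks <- unique(dt$mark)
  bins <- setdiff(names(dt), c("gene_id", "mark"))
  arr <- array(0, dim = c(length(genes), length(marks), length(bins)),
               dimnames = list(genes, marks, bins))
  for (m in marks) {
    sub <- dt[dt$mark == m, ]
    mat <- as.matrix(sub[, bins, with = FALSE])
    arr[match(sub$gene_id, genes), match(m, marks), ] <- mat
  }
  hm_profiles(arr)
}

#' Binarize expression at the per-sample median
#'
#' Labels a gene 1 ("high") when its expression exceeds the sample median.
#' Genes tied exactly at the median are assigned by stable rank so that the
#' two classes never differ in size by more than one gene.
#'
#' @param values non-negative finite expression values (length >= 2).
#' @return integer 0/1 vector, named like `values`.
#' @export
binarize_expression <- function(values) {
  if (length(values) < 2L) stop("need at least 2 expression values")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("expression values must be finite and non-negative")
  }
  if (length(unique(values)) == 1L) {
    stop("all expression values identical; median split is meaningless")
  }
  n <- length(values)
  r <- rank(values, ties.method = "first")
  labels <- as.integer(r > ceiling(n / 2))
  names(labels) <- names(values)
  labels
}

#' Split gene ids into train / validation / test sets
#'
#' Random permutation driven by `seed`: the first `n_train` ids form the
#' training set and the remainder is split as equally as possible, the
#' larger half going to validation.  `n_train` must be even so the
#' median-binarized training labels can be exactly balanced.
#'
#' @param gene_ids character vector of unique gene ids.
#' @param n_train number of training genes (even; default 6600).
#' @param seed integer seed; same seed, same split.
#' @return an `hm_split` list with `train`, `valid`, `test`, `seed`.
#' @examples
#' sp <- split_genes(paste0("g", 1:10), n_train = 6, seed = 1)
#' lengths(sp[c("train", "valid", "test")])
#' @export
split_genes <- function(gene_ids, n_train = 6600L, seed = 1L) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
  if (n_train %% 2L != 0L) {
    stop("n_train must be even: median binarization only yields balanced ",
         "training labels for an even training-set size")
  }
  if (n_train >= length(gene_ids)) stop("n_train must be < number of genes")
  perm <- withr::with_seed(seed, sample(gene_ids))
  rest <- perm[-seq_len(n_train)]
  n_valid <- ceiling(length(rest) / 2)
  structure(
    list(train = perm[seq_len(n_train)],
         valid = rest[seq_len(n_valid)],
         test  = rest[-seq_len(n_valid)],
         seed  = as.integer(seed)),
    class = "hm_split"
  )
}

#' @export
print.hm_split <- function(x, ...) {
  cat("<hm_split> train ", length(x$train), " / valid ", length(x$valid),
      " / test ", length(x$test), " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write / read a split manifest
#'
#' TSV with a `# seed: <int>` header line and columns `gene_id`, `set`.
#'
#' @param split an `hm_split` object.
#' @param path file path.
#' @export
write_split <- function(split, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seed: ", split$seed), con)
  df <- data.frame(
    gene_id = c(split$train, split$valid, split$test),
    set = rep(c("train", "valid", "test"),
              c(length(split$train), length(split$valid), length(split$test)))
  )
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  header <- readLines(path, n = 1L)
  seed <- as.integer(sub("^# seed:\\s*", "", header))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          stringsAsFactors = FALSE)
  structure(
    list(train = df$gene_id[df$set == "train"],
         valid = df$gene_id[df$set == "valid"],
         test  = df$gene_id[df$set == "test"],
         seed  = seed),
    class = "hm_split"
  )
}
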