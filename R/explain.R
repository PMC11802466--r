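# Parse the fitted tree ensemble into per-tree tables with, for every
# node, the cover-weighted expected leaf value of the subtree below it.
# The expected value of a leaf is its log-odds value; for an internal node
# it is the cover-weighted mean of its children's expected values, i.e.
# the prediction an "average" training gene reaching that node would get.
parse_trees <- function(model) {
  tt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model$booster))
  trees <- split(tt, tt$Tree)
  lapply(trees, function(tr) {
    n <- nrow(tr)
    tr <- tr[order(tr$Node), , drop = FALSE]
    row_of <- function(ids) match(ids, tr$ID)
    yes <- row_of(tr$Yes)
    no <- row_of(tr$No)
    miss <- row_of(tr$Missing)
    is_leaf <- tr$Feature == "Leaf"
    E <- ifelse(is_leaf, tr$Gain, NA_real_)
    for (i in rev(seq_len(n))) {
      if (is_leaf[i]) next
      cy <- tr$Cover[yes[i]]
      cn <- tr$Cover[no[i]]
      E[i] <- (E[yes[i]] * cy + E[no[i]] * cn) / (cy + cn)
    }
    if (anyNA(E)) stop("tree parse failed: unresolved expected values")
    list(feature = match(tr$Feature, model$feature_names),
         split = tr$Split, yes = yes, no = no, miss = miss,
         is_leaf = is_leaf, E = E)
  })
}

walk_tree <- function(tr, x, contrib) {
  i <- 1L
  while (!tr$is_leaf[i]) {
    fi <- tr$feature[i]
    xv <- x[fi]
    j <- if (is.na(xv)) tr$miss[i] else if (xv < tr$split[i]) tr$yes[i] else tr$no[i]
    contrib[fi] <- contrib[fi] + tr$E[j] - tr$E[i]
    i <- j
  }
  contrib
}

#' Decompose one prediction into per-feature log-odds contributions
#'
#' For every tree the gene's root-to-leaf path is walked; at each split
#' the change in the cover-weighted expected value between the node and
#' the chosen child is attributed to the split's feature.  The intercept
#' is the model's base log-odds plus the sum of the trees' root expected
#' values, so intercept + contributions equals the prediction's log-odds
#' exactly.
#'
#' @param model an `hm_model`.
#' @param feature_vector the gene's pattern counts (length = number of
#'   model patterns).
#' @param gene_id optional identifier carried along.
#' @return an `hm_explanation`: `intercept`, `contributions` (named),
#'   `logit`, `prob`, `counts`, `gene_id`.
#' @export
decompose_prediction <- function(model, feature_vector, gene_id = NULL) {
  if (length(feature_vector) != length(model$patterns)) {
    stop("feature vector length ", length(feature_vector),
         " does not match the model's ", length(model$patterns), " patterns")
  }
  ex <- explain_genes(model, matrix(feature_vector, nrow = 1L))
  structure(list(gene_id = gene_id, intercept = ex$intercept,
                 contributions = ex$contributions[1L, ],
                 logit = ex$logit[1L], prob = ex$prob[1L],
                 counts = stats::setNames(as.numeric(feature_vector),
                                          model$feature_names)),
            class = "hm_explanation")
}

#' @export
print.hm_explanation <- function(x, ...) {
  cat("<hm_explanation>",
      if (!is.null(x$gene_id)) paste0(" gene ", x$gene_id), "\n",
      "  intercept ", format(x$intercept, digits = 4),
      ", logit ", format(x$logit, digits = 4),
      ", prob ", format(x$prob, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Per-feature log-odds contributions for many genes
#'
#' Vectorized form of [decompose_prediction()].
#'
#' @param model an `hm_model`.
#' @param newdata `hm_profiles` or a feature matrix.
#' @return list with `intercept` (scalar), `contributions` (genes x
#'   features), `logit`, `prob`, and the feature matrix `counts`.
#' @export
explain_genes <- function(model, newdata) {
  fm <- model_feature_matrix(model, newdata)
  trees <- parse_trees(model)
  intercept <- sum(vapply(trees, function(tr) tr$E[1L], numeric(1)))
  K <- length(model$feature_names)
  G <- nrow(fm)
  contrib <- matrix(0, G, K, dimnames = list(rownames(fm), model$feature_names))
  for (g in seq_len(G)) {
    cg <- numeric(K)
    x <- fm[g, ]
    for (tr in trees) cg <- walk_tree(tr, x, cg)
    contrib[g, ] <- cg
  }
  logit <- intercept + rowSums(contrib)
  list(intercept = intercept, contributions = contrib, logit = logit,
       prob = stats::plogis(logit), counts = fm)
}

#' Per-bin relative importance map
#'
#' Distributes each pattern's absolute log-odds contribution for each gene
#' uniformly over the bins covered by that pattern's matches in the gene's
#' profile (each match covers its start bin through start + L - 1),
#' aggregates over genes (and models, when a list is given) and normalizes
#' the marks x bins map to sum to one.
#'
#' @param models an `hm_model` or a list of them.
#' @param profiles matching `hm_profiles` (or list of them) holding the
#'   genes to aggregate over, e.g. the test genes.
#' @return an `hm_importance` matrix (marks x bins, sums to 1) with the
#'   profile's mark names and signed bin labels.
#' @export
bin_importance <- function(models, profiles) {
  if (inherits(models, "hm_model")) models <- list(models)
  if (inherits(profiles, "hm_profiles")) profiles <- list(profiles)
  stopifnot(length(models) == length(profiles))
  d <- dim(profiles[[1L]])
  map <- matrix(0, d[2L], d[3L],
                dimnames = dimnames(profiles[[1L]])[c(2L, 3L)])
  for (s in seq_along(models)) {
    model <- models[[s]]
    prof <- profiles[[s]]
    ex <- explain_genes(model, prof)
    mark_mats <- lapply(seq_len(dim(prof)[2L]), function(m) mark_matrix(prof, m))
    for (k in seq_along(model$patterns)) {
      p <- model$patterns[[k]]
      L <- length(p$shape)
      P <- mark_mats[[p$mark]]
      rmat <- window_correlations(P, p$shape)
      hits <- !is.na(rmat) & rmat > p$cutoff
      for (g in seq_len(nrow(P))) {
        c_abs <- abs(ex$contributions[g, k])
        if (c_abs == 0) next
        starts <- which(hits[g, ])
        if (length(starts) == 0L) next  # no match: nothing to attribute
        w <- c_abs / (length(starts) * L)
        for (st in starts) {
          map[p$mark, st:(st + L - 1L)] <- map[p$mark, st:(st + L - 1L)] + w
        }
      }
    }
  }
  total <- sum(map)
  if (total > 0) map <- map / total
  structure(map, class = c("hm_importance", "matrix"))
}

#' Correlation between pattern frequency and contribution
#'
#' For each pattern, the Pearson correlation across genes between its
#' match count and its (signed) log-odds contribution; a positive value
#' means more matches push the classifier towards "high expression".
#' Patterns whose count is constant across the genes are skipped (their
#' correlation is undefined) and reported in `skipped`.
#'
#' @param contributions genes x patterns contribution matrix from
#'   [explain_genes()].
#' @param feature_matrix matching genes x patterns count matrix.
#' @param patterns the model's patterns (for mark grouping).
#' @param mark_names optional mark names for reporting.
#' @return list with `per_pattern` (pattern, mark, rho), `per_mark`
#'   (mark, n, mean_rho, sd_rho) and `skipped` (pattern indices).
#' @export
contribution_frequency_correlation <- function(contributions, feature_matrix,
                                               patterns, mark_names = NULL) {
  stopifnot(ncol(contributions) == length(patterns),
            ncol(feature_matrix) == length(patterns))
  if (nrow(feature_matrix) < 3L) stop("need at least 3 genes")
  rho <- rep(NA_real_, length(patterns))
  skipped <- integer(0)
  for (k in seq_along(patterns)) {
    cnt <- feature_matrix[, k]
    if (stats::sd(cnt) == 0) {
      skipped <- c(skipped, k)
      next
    }
    rho[k] <- stats::cor(cnt, contributions[, k])
  }
  if (length(skipped)) {
    message("skipped ", length(skipped),
            " pattern(s) with constant frequency: ",
            paste(skipped, collapse = ", "))
  }
  mk <- vapply(patterns, function(p) p$mark, integer(1))
  mark_lab <- if (is.null(mark_names)) as.character(mk) else mark_names[mk]
  keep <- setdiff(seq_along(patterns), skipped)
  per_pattern <- data.frame(pattern = keep, mark = mk[keep],
                            mark_name = mark_lab[keep], rho = rho[keep],
                            stringsAsFactors = FALSE)
  per_mark <- do.call(rbind, lapply(split(per_pattern, per_pattern$mark),
    function(d) data.frame(mark = d$mark[1L], mark_name = d$mark_name[1L],
                           n = nrow(d), mean_rho = mean(d$rho),
                           sd_rho = stats::sd(d$rho))))
  rownames(per_mark) <- NULL
  list(per_pattern = per_pattern, per_mark = per_mark, skipped = skipped)
}

#' Waterfall table for one explained prediction
#'
#' Orders features by absolute contribution (descending) and accumulates
#' the log-odds from the intercept so the running probability after each
#' feature can be read off directly.
#'
#' @param explanation an `hm_explanation`.
#' @return data.frame with columns `feature`, `count`, `contribution`,
#'   `cumulative_logit`, `cumulative_prob`; the first row is the
#'   intercept.
#' @export
waterfall_data <- function(explanation) {
  ord <- order(abs(explanation$contributions), decreasing = TRUE)
  contribs <- explanation$contributions[ord]
  cum <- explanation$intercept + cumsum(contribs)
  out <- data.frame(
    feature = c("intercept", names(contribs)),
    count = c(NA_real_, explanation$counts[ord]),
    contribution = c(explanation$intercept, unname(contribs)),
    cumulative_logit = c(explanation$intercept, unname(cum)),
    stringsAsFactors = FALSE
  )
  out$cumulative_prob <- stats::plogis(out$cumulative_logit)
  out
}

#' Waterfall plot of one prediction's feature contributions
#'
#' @param explanation an `hm_explanation`.
#' @param max_features show at most this many features (by absolute
#'   contribution).
#' @return a ggplot object.
#' @export
plot_waterfall <- function(explanation, max_features = 15L) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_waterfall needs the ggplot2 package")
  }
  wf <- waterfall_data(explanation)
  wf <- wf[seq_len(min(nrow(wf), max_features + 1L)), ]
  wf$label <- ifelse(is.na(wf$count), wf$feature,
                     paste0(wf$feature, " (n=", wf$count, ")"))
  wf$label <- factor(wf$label, levels = wf$label)
  wf$from <- c(0, utils::head(wf$cumulative_logit, -1L))
  ggplot2::ggplot(wf, ggplot2::aes(x = label)) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = as.numeric(label) - 0.4,
      xmax = as.numeric(label) + 0.4,
      ymin = from, ymax = cumulative_logit,
      fill = contribution > 0)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = "cumulative log-odds") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
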