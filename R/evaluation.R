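# Evaluation machinery: protein-level random splits, ROC/PR curves with
# vertical averaging, precision-vs-confidence filtering, and score-bin
# enrichment analysis with rank correlations.

#' Protein-level random train/test splits
#'
#' Every variant of a protein falls wholly in train or wholly in test;
#' fractions are computed over proteins, not variants.  Deterministic given
#' `seed`.
#'
#' @param protein character vector: the protein of each record (or a
#'   data.frame with a `protein` column).
#' @param n_splits number of random splits (default 100).
#' @param train_frac fraction of proteins assigned to training
#'   (default 0.8).
#' @param seed integer seed.
#' @return list of `n_splits` lists with integer index vectors `train` and
#'   `test`.
#' @export
protein_level_splits <- function(protein, n_splits = 100, train_frac = 0.8,
                                 seed = 1) {
  if (is.data.frame(protein)) protein <- protein$protein
  prots <- unique(protein)
  if (length(prots) < 5)
    stop("split error: need at least 5 proteins for protein-level splits",
         call. = FALSE)
  n_train <- round(train_frac * length(prots))
  if (n_train < 1 || n_train >= length(prots))
    stop("split error: train_frac leaves an empty side", call. = FALSE)
  set.seed(seed)
  lapply(seq_len(n_splits), function(s) {
    tr <- sample(prots, n_train)
    list(train = which(protein %in% tr), test = which(!protein %in% tr))
  })
}

#' ROC and PR curves with areas
#'
#' Sweeps thresholds over the unique scores (ties grouped).  AUROC is the
#' trapezoidal area under the ROC curve, which equals the Mann-Whitney
#' concordance probability.  AUPR integrates the step-wise precision
#' envelope (the best precision achievable at or beyond each recall), which
#' avoids the optimism of linear interpolation in PR space.
#'
#' @param scores numeric scores, higher = more deleterious.
#' @param labels deleterious/neutral (or 1/0) truth labels.
#' @return object of class `eval_curves`: list with `roc_points`
#'   (data.frame `fpr`, `tpr`), `pr_points` (data.frame `recall`,
#'   `precision`), `auroc`, `aupr`.
#' @export
roc_pr <- function(scores, labels) {
  y <- label01(labels)
  if (length(unique(y)) < 2)
    stop("degenerate input: both classes are required", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  P <- sum(y == 1); N <- sum(y == 0)
  # group tied scores: cumulative counts at the end of each tie group
  last_of_group <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y == 1)[last_of_group]
  fp <- cumsum(y == 0)[last_of_group]
  roc <- data.frame(fpr = c(0, fp / N), tpr = c(0, tp / P))
  auroc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  recall <- tp / P
  precision <- tp / (tp + fp)
  # precision envelope: best precision at recall >= r
  env <- rev(cummax(rev(precision)))
  aupr <- sum(diff(c(0, recall)) * env)
  pr <- data.frame(recall = recall, precision = precision)
  structure(list(roc_points = roc, pr_points = pr,
                 auroc = auroc, aupr = aupr),
            class = "eval_curves")
}

#' @export
print.eval_curves <- function(x, ...) {
  cat(sprintf("evaluation curves: AUROC %.4f, AUPR %.4f (%d ROC points)\n",
              x$auroc, x$aupr, nrow(x$roc_points)))
  invisible(x)
}

#' Vertically average a list of evaluation curves
#'
#' ROC curves are averaged at 101 evenly spaced false-positive rates and PR
#' curves at 101 evenly spaced recalls; the averaged areas are the means of
#' the member areas.
#'
#' @param curves list of `eval_curves`.
#' @param grid_points number of sweep-grid points (default 101).
#' @return an `eval_curves` object.
#' @export
average_curves <- function(curves, grid_points = 101) {
  if (!length(curves)) stop("average_curves() needs at least one curve", call. = FALSE)
  stopifnot(all(vapply(curves, inherits, TRUE, "eval_curves")))
  grid <- seq(0, 1, length.out = grid_points)
  interp <- function(x, y, at) stats::approx(x, y, xout = at, rule = 2,
                                             ties = max)$y
  tpr <- rowMeans(vapply(curves, function(cv)
    interp(cv$roc_points$fpr, cv$roc_points$tpr, grid), numeric(grid_points)))
  prec <- rowMeans(vapply(curves, function(cv)
    interp(cv$pr_points$recall, cv$pr_points$precision, grid),
    numeric(grid_points)))
  structure(list(roc_points = data.frame(fpr = grid, tpr = tpr),
                 pr_points = data.frame(recall = grid, precision = prec),
                 auroc = mean(vapply(curves, `[[`, numeric(1), "auroc")),
                 aupr = mean(vapply(curves, `[[`, numeric(1), "aupr"))),
            class = "eval_curves")
}

#' Precision among predictions above a confidence cutoff
#'
#' @param scores numeric scores.
#' @param labels truth labels.
#' @param cutoff predictions with `score > cutoff` (strict) are counted.
#' @return list with `precision`, `fraction_above` and `empty` (TRUE when
#'   nothing scores above the cutoff, in which case precision is `NA`).
#' @export
precision_at_cutoff <- function(scores, labels, cutoff) {
  y <- label01(labels)
  above <- scores > cutoff
  if (!any(above))
    return(list(precision = NA_real_, fraction_above = 0, empty = TRUE))
  list(precision = mean(y[above] == 1),
       fraction_above = mean(above),
       empty = FALSE)
}

#' Score-bin enrichment of one cohort over another
#'
#' Bins two score sets (e.g. proband and unaffected-sibling mutations) into
#' equal-width bins on \[0, 1\], forms the per-bin count ratio A/B, and
#' correlates bin midpoint with ratio (Spearman and Pearson) over the bins
#' where the ratio is defined.  Bins with zero denominator are flagged, not
#' silently dropped.  The background line is `length(A)/length(B)`.
#'
#' @param scores_A,scores_B numeric scores in \[0, 1\].
#' @param n_bins number of equal-width bins (default 10).
#' @return object of class `enrichment_table`: data.frame-like list with
#'   `bin_edges`, `midpoints`, `counts_A`, `counts_B`, `ratio`, `defined`,
#'   `background`, `spearman`, `spearman_p`, `pearson`, `pearson_p`.
#' @export
enrichment_by_bins <- function(scores_A, scores_B, n_bins = 10) {
  if (n_bins < 2) stop("config error: n_bins must be at least 2", call. = FALSE)
  rng_ok <- function(x) all(x >= 0 & x <= 1)
  if (!rng_ok(scores_A) || !rng_ok(scores_B))
    stop("scores must lie in [0, 1]", call. = FALSE)
  edges <- seq(0, 1, length.out = n_bins + 1)
  binof <- function(x) pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
                            n_bins)
  counts_A <- tabulate(binof(scores_A), nbins = n_bins)
  counts_B <- tabulate(binof(scores_B), nbins = n_bins)
  ratio <- ifelse(counts_B > 0, counts_A / counts_B, NA_real_)
  defined <- counts_B > 0
  mid <- (utils::head(edges, -1) + utils::tail(edges, -1)) / 2
  sp <- pe <- list(estimate = NA_real_, p.value = NA_real_)
  if (sum(defined) >= 3) {
    exact <- n_bins <= 12
    sp <- suppressWarnings(stats::cor.test(mid[defined], ratio[defined],
                                           method = "spearman", exact = exact))
    pe <- stats::cor.test(mid[defined], ratio[defined], method = "pearson")
  }
  structure(list(bin_edges = edges, midpoints = mid,
                 counts_A = counts_A, counts_B = counts_B,
                 ratio = ratio, defined = defined,
                 background = length(scores_A) / length(scores_B),
                 spearman = unname(sp$estimate), spearman_p = sp$p.value,
                 pearson = unname(pe$estimate), pearson_p = pe$p.value),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  df <- data.frame(bin = sprintf("[%.2f,%.2f]", utils::head(x$bin_edges, -1),
                                 utils::tail(x$bin_edges, -1)),
                   A = x$counts_A, B = x$counts_B,
                   ratio = round(x$ratio, 2))
  print(df, row.names = FALSE)
  cat(sprintf("background %.2f; Spearman %.2f (p=%.3g), Pearson %.2f (p=%.3g)\n",
              x$background, x$spearman, x$spearman_p, x$pearson, x$pearson_p))
  invisible(x)
}

#' Enrichment ratios from a 2x2 contingency of predictions
#'
#' For cohorts A and B split into deleterious/neutral calls at a score
#' threshold: `pos_ratio = a_pos/b_pos` (enrichment of A among deleterious
#' calls) and `neg_ratio = a_neg/b_neg` (among neutral calls), each
#' reported to 2 decimals.  A zero denominator yields `NA` for that ratio.
#'
#' @param a_pos,a_neg,b_pos,b_neg non-negative counts.
#' @return named numeric vector `c(pos_ratio, neg_ratio)`.
#' @examples
#' contingency_enrichment(554, 781, 348, 543)  # 1.59, 1.44
#' @export
contingency_enrichment <- function(a_pos, a_neg, b_pos, b_neg) {
  stopifnot(a_pos >= 0, a_neg >= 0, b_pos >= 0, b_neg >= 0)
  pos <- if (b_pos > 0) round(a_pos / b_pos, 2) else NA_real_
  neg <- if (b_neg > 0) round(a_neg / b_neg, 2) else NA_real_
  c(pos_ratio = pos, neg_ratio = neg)
}

#' Plot evaluation curves
#' @param x an `eval_curves` object.
#' @param which `"roc"`, `"pr"` or `"both"`.
#' @param ... passed to `plot`.
#' @export
plot.eval_curves <- function(x, which = c("both", "roc", "pr"), ...) {
  which <- match.arg(which)
  op <- graphics::par(no.readonly = TRUE); on.exit(graphics::par(op))
  if (which == "both") graphics::par(mfrow = c(1, 2))
  if (which %in% c("both", "roc")) {
    graphics::plot(x$roc_points$fpr, x$roc_points$tpr, type = "l",
                   xlab = "false positive rate", ylab = "true positive rate",
                   main = sprintf("ROC (AUROC %.3f)", x$auroc), ...)
    graphics::abline(0, 1, lty = 3)
  }
  if (which %in% c("both", "pr")) {
    graphics::plot(x$pr_points$recall, x$pr_points$precision, type = "l",
                   ylim = c(0, 1), xlab = "recall", ylab = "precision",
                   main = sprintf("PR (AUPR %.3f)", x$aupr), ...)
  }
  invisible(x)
}
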