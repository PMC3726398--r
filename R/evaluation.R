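#' Confusion counts at a threshold
#'
#' Counts true/false positives and negatives of the edge calls obtained by
#' thresholding a score matrix at `p_th` (edge predicted iff `score >=
#' p_th`), against a reference adjacency. Counts run over ordered
#' off-diagonal pairs; self-edges are excluded everywhere.
#'
#' @param scores n x n score matrix (posterior probabilities or absolute
#'   coefficients); `scores[i, j]` scores the edge `j -> i`.
#' @param truth n x n reference adjacency (nonzero = edge present).
#' @param p_th Threshold.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_at_threshold <- function(scores, truth, p_th) {
  scores <- as.matrix(scores); truth <- as.matrix(truth)
  if (!all(dim(scores) == dim(truth)))
    stop("score and reference matrices must have matching dimensions")
  off <- !diag(nrow(scores))
  pred <- !is.na(scores) & scores >= p_th
  pos <- truth != 0
  c(TP = sum(pred[off] & pos[off]),
    FP = sum(pred[off] & !pos[off]),
    TN = sum(!pred[off] & !pos[off]),
    FN = sum(!pred[off] & pos[off]))
}

#' ROC and PR curves with areas, by threshold sweep
#'
#' Sweeps the edge-calling threshold over a grid, computes the ROC (FP
#' rate vs TP rate) and precision-recall curves, and integrates both by
#' the trapezoidal rule. For probability matrices the default grid is 0 to
#' 1 in steps of 0.01; for unbounded coefficient matrices thresholds are
#' placed at every unique absolute score plus sentinels, which makes the
#' swept AUROC equal the midrank Mann-Whitney statistic. Precision at zero
#' predictions is taken as 1 (standard PR-curve closure).
#'
#' @param scores n x n score matrix (`scores[i, j]` scores `j -> i`).
#'   Coefficient matrices are evaluated on absolute values.
#' @param truth n x n reference adjacency (nonzero = edge).
#' @param grid Threshold grid; `NULL` (default) picks `seq(0, 1, 0.01)`
#'   when all scores lie in [0, 1] and the unique-absolute-values grid
#'   otherwise. Pass `"exact"` to force the unique-values grid.
#' @return An object of class `"bvsa_eval"`: list with `roc` and `pr`
#'   data frames, `auroc`, `aupr`, `grid`.
#' @export
evaluate_network <- function(scores, truth, grid = NULL) {
  scores <- as.matrix(scores); truth <- as.matrix(truth)
  if (!all(dim(scores) == dim(truth)))
    stop("score and reference matrices must have matching dimensions")
  off <- !diag(nrow(scores))
  s <- scores[off]
  y <- truth[off] != 0
  if (!any(y)) stop("reference network has no edges: AUPR undefined")
  if (any(is.na(s))) stop("NA scores among off-diagonal entries")
  probs <- all(s >= 0 & s <= 1)
  if (!probs) s <- abs(s)
  if (is.null(grid)) {
    grid <- if (probs) seq(0, 1, by = 0.01) else
      sort(unique(c(0, s, max(s) * (1 + 1e-9) + 1e-12)))
  } else if (identical(grid, "exact")) {
    grid <- sort(unique(c(0, s, max(s) * (1 + 1e-9) + 1e-12)))
  }
  grid <- sort(unique(c(grid, max(s) * (1 + 1e-9) + 1e-12)))

  npos <- sum(y); nneg <- sum(!y)
  pts <- t(vapply(grid, function(th) {
    pred <- s >= th
    tp <- sum(pred & y); fp <- sum(pred & !y)
    c(th = th, tpr = tp / npos,
      fpr = if (nneg) fp / nneg else 0,
      precision = if (tp + fp) tp / (tp + fp) else 1)
  }, numeric(4)))

  roc <- data.frame(threshold = pts[, "th"], fpr = pts[, "fpr"],
                    tpr = pts[, "tpr"])
  pr <- data.frame(threshold = pts[, "th"], recall = pts[, "tpr"],
                   precision = pts[, "precision"])
  auroc <- trapezoid(rev(roc$fpr), rev(roc$tpr))
  aupr <- trapezoid(rev(pr$recall), rev(pr$precision))
  structure(list(roc = roc, pr = pr, auroc = auroc, aupr = aupr,
                 grid = grid),
            class = "bvsa_eval")
}

trapezoid <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' @export
print.bvsa_eval <- function(x, ...) {
  cat(sprintf("Network evaluation: AUROC = %.4f, AUPR = %.4f (%d thresholds)\n",
              x$auroc, x$aupr, length(x$grid)))
  invisible(x)
}

#' Plot ROC and PR curves
#'
#' @param x A [evaluate_network()] result.
#' @param which `"roc"`, `"pr"`, or `"both"` (default).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bvsa_eval <- function(x, which = c("both", "roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "both") {
    old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  }
  if (which != "pr") {
    graphics::plot(x$roc$fpr, x$roc$tpr, type = "l", xlim = 0:1,
                   ylim = 0:1, xlab = "FP rate", ylab = "TP rate",
                   main = sprintf("ROC (AUROC %.3f)", x$auroc), ...)
    graphics::abline(0, 1, lty = 3)
  }
  if (which != "roc")
    graphics::plot(x$pr$recall, x$pr$precision, type = "l", xlim = 0:1,
                   ylim = 0:1, xlab = "recall", ylab = "precision",
                   main = sprintf("PR (AUPR %.3f)", x$aupr), ...)
  invisible(x)
}

#' Summarize repeated evaluation runs
#'
#' Means and standard deviations of AUROC and AUPR across repeated
#' inference runs — the headline performance summary for simulation
#' studies.
#'
#' @param results List of [evaluate_network()] results (>= 2).
#' @return A one-row `data.frame`: `auroc_mean`, `auroc_sd`, `aupr_mean`,
#'   `aupr_sd`, `n_runs`.
#' @export
summarize_runs <- function(results) {
  if (length(results) < 2) stop("need at least two runs to summarize")
  auroc <- vapply(results, function(r) r$auroc, numeric(1))
  aupr <- vapply(results, function(r) r$aupr, numeric(1))
  data.frame(auroc_mean = mean(auroc), auroc_sd = sd(auroc),
             aupr_mean = mean(aupr), aupr_sd = sd(aupr),
             n_runs = length(results))
}
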