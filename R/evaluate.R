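# Evaluation: confusion counts, recall/precision/F across E-value cutoffs,
# and the precision-decrement trapezoid AUC.

#' Confusion counts and rates between predicted and truth read sets
#'
#' `TP = |pred ∩ truth|`, `FP = |pred \ truth|`, `FN = |truth \ pred|`;
#' `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`, F their harmonic mean.
#' A rate with zero denominator is reported as 0 and flagged in
#' `undefined`.
#'
#' @param predicted,truth character vectors of read ids.
#' @return an object of class `eval_counts` with fields `tp`, `fp`, `fn`,
#'   `recall`, `precision`, `f_measure`, `undefined`.
#' @export
confusion_counts <- function(predicted, truth) {
  predicted <- unique(as.character(predicted))
  truth <- unique(as.character(truth))
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  undef <- c(recall = tp + fn == 0L, precision = tp + fp == 0L)
  recall <- if (undef[["recall"]]) 0 else tp / (tp + fn)
  precision <- if (undef[["precision"]]) 0 else tp / (tp + fp)
  f <- if (recall + precision == 0) 0 else
    2 * recall * precision / (recall + precision)
  structure(list(tp = tp, fp = fp, fn = fn, recall = recall,
                 precision = precision, f_measure = f, undefined = undef),
            class = c("eval_counts", "pepgrasp_obj"))
}

#' @export
format.eval_counts <- function(x, ...) {
  sprintf("<eval_counts tp=%d fp=%d fn=%d recall=%.3f precision=%.3f F=%.3f>",
          x$tp, x$fp, x$fn, x$recall, x$precision, x$f_measure)
}

#' Default E-value cutoff ladder (1e-10 .. 10)
#' @export
default_cutoffs <- function() 10^seq(-10, 1)

#' Per-read best E-values from post-mapping assignments
#'
#' A read's E-value is the minimum E-value over all contigs it maps to.
#'
#' @param assignments output of [post_map()].
#' @param contigs the [contig_set()] (or contig list) the assignments refer to.
#' @return named numeric vector (read id -> best E-value).
#' @export
read_best_evalues <- function(assignments, contigs) {
  cts <- if (inherits(contigs, "contig_set")) contigs$contigs else contigs
  if (nrow(assignments) == 0L) return(setNames(numeric(0), character(0)))
  ev <- vapply(cts, `[[`, 0, "evalue")[assignments$contig]
  best <- tapply(ev, assignments$read_id, min)
  setNames(as.numeric(best), names(best))
}

#' Recall/precision curve across ascending E-value cutoffs
#'
#' Point k uses the prediction set `{reads with E <= cutoff_k}`; the
#' prediction sets are nested, so TP is non-decreasing in k.
#'
#' @param evalues named numeric vector of per-read best E-values
#'   ([read_best_evalues()]).
#' @param truth character vector of ground-truth read ids.
#' @param cutoffs strictly ascending E-value cutoffs.
#' @return an object of class `eval_curve` with `cutoffs`, `points`
#'   (data.frame `cutoff`, `tp`, `fp`, `fn`, `recall`, `precision`,
#'   `f_measure`) and `auc`.
#' @export
roc_curve <- function(evalues, truth, cutoffs = default_cutoffs()) {
  stopifnot(length(cutoffs) >= 1L)
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be strictly ascending")
  pts <- lapply(cutoffs, function(cut) {
    cc <- confusion_counts(names(evalues)[evalues <= cut], truth)
    data.frame(cutoff = cut, tp = cc$tp, fp = cc$fp, fn = cc$fn,
               recall = cc$recall, precision = cc$precision,
               f_measure = cc$f_measure)
  })
  points <- do.call(rbind, pts)
  curve <- structure(list(cutoffs = cutoffs, points = points, auc = NA_real_),
                     class = c("eval_curve", "pepgrasp_obj"))
  if (nrow(points) >= 2L) curve$auc <- auc(curve)
  curve
}

#' @export
format.eval_curve <- function(x, ...) {
  sprintf("<eval_curve: %d cutoffs [%g..%g], AUC=%s>",
          length(x$cutoffs), min(x$cutoffs), max(x$cutoffs),
          format(x$auc, digits = 4))
}

#' Area under the recall/precision curve
#'
#' The precision-decrement trapezoid sum
#' `sum_k (recall_{k+1} + recall_k) * (precision_k - precision_{k+1}) / 2`
#' over consecutive ascending-cutoff points.  Note this is not the classical
#' ROC integral: a curve with constant precision has AUC 0 because no
#' precision decrement is ever accumulated.
#'
#' @param curve an `eval_curve`, or a data.frame with `recall` and
#'   `precision` columns ordered by ascending cutoff.
#' @return the trapezoid sum.
#' @export
auc <- function(curve) {
  pts <- if (inherits(curve, "eval_curve")) curve$points else curve
  stopifnot(is.data.frame(pts), all(c("recall", "precision") %in% names(pts)))
  n <- nrow(pts)
  if (n < 2L) stop("AUC requires at least 2 curve points")
  r <- pts$recall; p <- pts$precision
  sum((r[-1] + r[-n]) * (p[-n] - p[-1]) / 2)
}

#' Evaluate a search result against ground truth
#'
#' @param assignments output of [post_map()].
#' @param contigs the corresponding [contig_set()] or contig list.
#' @param truth character vector of ground-truth read ids.
#' @param cutoffs ascending E-value cutoffs.
#' @return list with `curve` (an `eval_curve`) and `counts` (the
#'   [confusion_counts()] of the full homolog set).
#' @export
evaluate_search <- function(assignments, contigs, truth,
                            cutoffs = default_cutoffs()) {
  ev <- read_best_evalues(assignments, contigs)
  list(curve = roc_curve(ev, truth, cutoffs),
       counts = confusion_counts(names(ev), truth))
}
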