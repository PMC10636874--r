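#' Truth set of experimentally verified lncRNA GO terms
#'
#' @param terms_by_lncrna Named list: one nonempty character vector of GO
#'   terms per lncRNA.
#' @return A list of class `truth_set` with `terms` and `n_test`.
#' @export
truth_set <- function(terms_by_lncrna) {
  if (length(terms_by_lncrna) == 0) stop("truth set is empty")
  if (is.null(names(terms_by_lncrna)) || any(names(terms_by_lncrna) == ""))
    stop("truth set entries must be named by lncRNA id")
  lens <- vapply(terms_by_lncrna, length, integer(1))
  if (any(lens == 0))
    stop("empty truth term set for: ",
         paste(names(terms_by_lncrna)[lens == 0], collapse = ", "))
  terms <- lapply(terms_by_lncrna, function(x) sort(unique(as.character(x))))
  structure(list(terms = terms, n_test = length(terms)), class = "truth_set")
}

#' Per-gene precision and recall at a threshold
#'
#' `precision = |P  intersect T| / |P|` (NA when the prediction set is empty:
#' such genes are excluded from the averaged precision via the m(t)
#' convention), `recall = |P intersect T| / |T|`.
#'
#' @param predicted Character vector of predicted terms (may be empty).
#' @param truth Nonempty character vector of true terms.
#' @return Named numeric vector `c(precision =, recall =)`.
#' @export
per_gene_pr <- function(predicted, truth) {
  truth <- unique(truth)
  if (length(truth) == 0) stop("truth term set must be nonempty")
  predicted <- unique(predicted)
  tp <- length(intersect(predicted, truth))
  c(precision = if (length(predicted) == 0) NA_real_ else tp / length(predicted),
    recall = tp / length(truth))
}

#' Thresholded prediction sets
#'
#' Terms whose score is greater than **or equal to** the threshold are
#' predicted (boundary scores are included).
#'
#' @param predictions A `prediction_matrix` (lncRNAs x terms).
#' @param t Threshold in \[0, 1\].
#' @return Named list of character vectors, one per lncRNA row.
#' @export
threshold_predictions <- function(predictions, t) {
  stopifnot(t >= 0, t <= 1)
  terms <- colnames(predictions)
  out <- lapply(seq_len(nrow(predictions)), function(i)
    terms[predictions[i, ] >= t])
  names(out) <- rownames(predictions)
  out
}

#' Averaged precision-recall curve over a threshold grid
#'
#' At each threshold t: `m(t)` counts the evaluated lncRNAs with at least one
#' score >= t; averaged precision is the mean of per-gene precision over
#' those m(t) lncRNAs (NA when m(t) = 0, excluded from the Fmax search);
#' averaged recall is the mean of per-gene recall over all N evaluated
#' lncRNAs, where an lncRNA with an empty prediction set contributes
#' recall 0.
#'
#' Only lncRNAs present in the truth set are evaluated; a truth lncRNA with
#' no prediction row contributes recall 0 everywhere and never enters m(t).
#'
#' @param predictions A `prediction_matrix`.
#' @param truth A [truth_set()].
#' @param grid Thresholds in \[0, 1\] (default 101 evenly spaced values).
#' @return data.frame of class `pr_curve`: `threshold`, `m`, `precision`,
#'   `recall`.
#' @export
pr_curve <- function(predictions, truth, grid = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(truth, "truth_set"))
  if (any(grid < 0 | grid > 1)) stop("grid thresholds must be in [0, 1]")
  lnc <- names(truth$terms)
  n <- truth$n_test
  have_row <- lnc[lnc %in% rownames(predictions)]
  res <- lapply(grid, function(t) {
    prec <- numeric(0)
    rec_sum <- 0
    for (id in have_row) {
      p_i <- colnames(predictions)[predictions[id, ] >= t]
      pr <- per_gene_pr(p_i, truth$terms[[id]])
      if (length(p_i) > 0) prec <- c(prec, pr[["precision"]])
      rec_sum <- rec_sum + pr[["recall"]]
    }
    m <- length(prec)
    c(threshold = t, m = m,
      precision = if (m > 0) mean(prec) else NA_real_,
      recall = rec_sum / n)
  })
  out <- as.data.frame(do.call(rbind, res))
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Maximum F-measure over the threshold grid
#'
#' `Fmax = max_t 2 Pr(t) Rc(t) / (Pr(t) + Rc(t))`, taken over thresholds with
#' a defined averaged precision (m(t) > 0); F is 0 where Pr + Rc = 0. Ties
#' resolve to the smallest threshold.
#'
#' @param curve A [pr_curve()].
#' @return A list of class `evaluation_summary`: `fmax`, `t_star`,
#'   `precision`, `recall` (the averaged values at `t_star`).
#' @export
fmax <- function(curve) {
  ok <- !is.na(curve$precision)
  if (!any(ok)) stop("no threshold with defined precision (m(t) = 0 everywhere)")
  pr <- curve$precision[ok]; rc <- curve$recall[ok]; th <- curve$threshold[ok]
  f <- ifelse(pr + rc > 0, 2 * pr * rc / (pr + rc), 0)
  i <- which.max(f)
  structure(list(fmax = f[i], t_star = th[i], precision = pr[i],
                 recall = rc[i]),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("Fmax = %.3f at t* = %.2f (precision %.3f, recall %.3f)\n",
              x$fmax, x$t_star, x$precision, x$recall))
  invisible(x)
}

#' Number of correctly annotated lncRNAs
#'
#' Counts the evaluated lncRNAs with at least one true positive term at the
#' given threshold (by default the threshold should be the Fmax argmax).
#'
#' @param predictions A `prediction_matrix`.
#' @param truth A [truth_set()].
#' @param t Score threshold in \[0, 1\].
#' @return Integer count in `0..n_test`.
#' @export
count_correct <- function(predictions, truth, t) {
  stopifnot(inherits(truth, "truth_set"), t >= 0, t <= 1)
  n <- 0L
  for (id in names(truth$terms)) {
    if (!id %in% rownames(predictions)) next
    p_i <- colnames(predictions)[predictions[id, ] >= t]
    if (length(intersect(p_i, truth$terms[[id]])) >= 1) n <- n + 1L
  }
  n
}

#' Fmax of a permuted-truth baseline
#'
#' Randomly reassigns the truth term sets among the evaluated lncRNAs and
#' recomputes Fmax; the resulting chance-level score reflects only the term
#' frequencies, not any lncRNA-specific signal.
#'
#' @param predictions A `prediction_matrix`.
#' @param truth A [truth_set()].
#' @param seed Integer seed for the permutation.
#' @param grid Threshold grid (see [pr_curve()]).
#' @return An `evaluation_summary` for the permuted truth.
#' @export
permuted_truth_fmax <- function(predictions, truth, seed = 1,
                                grid = seq(0, 1, by = 0.01)) {
  set.seed(seed)
  perm <- sample(length(truth$terms))
  shuffled <- truth$terms[perm]
  names(shuffled) <- names(truth$terms)
  fmax(pr_curve(predictions, truth_set(shuffled), grid))
}
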