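# evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Confusion-matrix metrics
#'
#' Derives the standard binary-classification metrics from TP/FP/TN/FN
#' counts: TPR (= recall), FPR, TNR, FNR, accuracy, precision and the F1
#' score (harmonic mean of precision and recall, `2TP / (2TP + FP + FN)`).
#' A metric whose denominator is zero is reported as `NA`.
#'
#' @param tp,fp,tn,fn non-negative integer counts; not all zero.
#' @return named numeric vector with elements TPR, FPR, TNR, FNR,
#'   accuracy, precision, recall, F1.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("all confusion counts are zero")
  div <- function(a, b) if (b > 0) a / b else NA_real_
  tpr <- div(tp, tp + fn)
  fpr <- div(fp, fp + tn)
  precision <- div(tp, tp + fp)
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  c(TPR = tpr, FPR = fpr,
    TNR = div(tn, tn + fp), FNR = div(fn, tp + fn),
    accuracy = (tp + tn) / sum(counts),
    precision = precision, recall = tpr, F1 = f1)
}

#' Did the true kinase make the top k?
#'
#' @param ranked ordered kinase ids (character vector, or a data.table with
#'   a `kinase_id` column as returned by the ranking functions).
#' @param true_kinase kinase id to look for.
#' @param k cut-off rank (>= 1).
#' @return logical.
#' @export
topk_hit <- function(ranked, true_kinase, k = 10L) {
  stopifnot(k >= 1L)
  ids <- if (is.data.frame(ranked)) ranked$kinase_id else as.character(ranked)
  true_kinase %in% utils::head(ids, k)
}

take_rows <- function(x, idx) {
  if (is.data.frame(x)) x[idx, , drop = FALSE] else x[idx]
}

#' k-fold cross-validated top-k accuracy
#'
#' Partitions the kinase-substrate pairs into `folds` near-equal folds by a
#' seeded shuffle. For each fold, `scorer(train_pairs)` must rebuild every
#' model (network, affinity graph, sequence models) from the training pairs
#' only and return a ranking function `function(site_row) -> ordered kinase
#' ids`; fold accuracy is the fraction of held-out pairs whose kinase
#' appears in the top `k` of the ranking for their site.
#'
#' @param pairs pair table (one row per kinase-substrate site).
#' @param scorer model factory as described above.
#' @param folds number of folds (>= 2, default 10).
#' @param k top-k cut-off.
#' @param seed integer seed for the fold assignment.
#' @return numeric vector of per-fold accuracies (length `folds`).
#' @export
kfold_topk_accuracy <- function(pairs, scorer, folds = 10L, k = 10L,
                                seed = 1L) {
  n <- nrow(pairs)
  stopifnot(folds >= 2L, n >= folds)
  fold_of <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    test_idx <- which(fold_of == f)
    if (length(test_idx) == 0L) stop("fold ", f, " has no test pairs")
    rank_fn <- scorer(take_rows(pairs, -test_idx))
    hits <- vapply(test_idx, function(i) {
      row <- take_rows(pairs, i)
      topk_hit(rank_fn(row), row$kinase_id, k)
    }, logical(1))
    acc[f] <- mean(hits)
  }
  acc
}

#' Per-kinase 7:3 split with matched negatives
#'
#' Splits one kinase's positive sites into a training set and a positive
#' test set at a 7:3 ratio (test size `floor(0.3 * n)`, remainder to
#' train), then samples an equal number of negatives without replacement
#' so the test set is balanced 1:1. Negatives come half from phosphosites
#' of other kinases and half from windows around S/T/Y residues with no
#' known phosphorylation; when one pool is too small the other tops up
#' the difference.
#'
#' @param sites positives of one kinase (vector or data.frame of sites).
#' @param other_kinase_sites negative pool 1: other kinases' phosphosites.
#' @param nonphospho_windows negative pool 2: unannotated S/T/Y windows.
#' @param seed integer seed.
#' @param train_fraction fraction of positives kept for training
#'   (default 0.7).
#' @return list with `train` (positives), `test` (positives then
#'   negatives), `labels` (logical vector, TRUE = positive) and the
#'   per-pool negative counts in `n_neg_sites` / `n_neg_windows`.
#' @export
per_kinase_split <- function(sites, other_kinase_sites, nonphospho_windows,
                             seed = 1L, train_fraction = 0.7) {
  n <- NROW(sites)
  if (n < 2L) stop("need at least 2 positive sites to split")
  n_test <- as.integer(floor((1 - train_fraction) * n))
  if (n_test < 1L) stop("split leaves no positive test sites")
  n1 <- NROW(other_kinase_sites)
  n2 <- NROW(nonphospho_windows)
  if (n1 + n2 < n_test)
    stop("insufficient negatives: need ", n_test, ", have ", n1 + n2)
  with_seed(seed, {
    test_idx <- sample(n, n_test)
    # half from each negative pool; top up from the larger pool if short
    want1 <- min(n1, as.integer(ceiling(n_test / 2)))
    want2 <- min(n2, n_test - want1)
    want1 <- as.integer(n_test - want2)
    want2 <- as.integer(want2)
    neg1 <- if (want1 > 0) sample(n1, want1) else integer(0)
    neg2 <- if (want2 > 0) sample(n2, want2) else integer(0)
    list(train = take_rows(sites, setdiff(seq_len(n), test_idx)),
         test = c_rows(take_rows(sites, test_idx),
                       c_rows(take_rows(other_kinase_sites, neg1),
                              take_rows(nonphospho_windows, neg2))),
         labels = c(rep(TRUE, n_test), rep(FALSE, want1 + want2)),
         n_neg_sites = want1, n_neg_windows = want2)
  })
}

c_rows <- function(a, b) {
  if (is.data.frame(a) || is.data.frame(b)) {
    data.table::rbindlist(list(
      data.table::as.data.table(a), data.table::as.data.table(b)))
  } else c(a, b)
}

#' ROC and precision-recall curves from scored examples
#'
#' Sweeps a threshold down the unique score values (tied scores grouped at
#' one threshold), accumulating TP/FP counts, and returns the ROC path
#' with its trapezoidal area (AUROC) plus the precision-recall path with
#' its trapezoidal area (AUPRC). With grouped ties, the trapezoidal AUROC
#' equals the concordant-pair fraction counting ties as 1/2.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels logical (or 0/1) true labels; both classes must occur.
#' @return list with `roc` (data.table fpr, tpr, threshold), `auroc`,
#'   `pr` (data.table recall, precision, threshold), `auprc`.
#' @export
roc_pr_curves <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to draw ROC/PR curves")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  last <- !duplicated(s, fromLast = TRUE)  # group ties at one threshold
  cum_tp <- cumsum(y)[last]
  cum_fp <- cumsum(!y)[last]
  thr <- s[last]
  tpr <- cum_tp / n_pos
  fpr <- cum_fp / n_neg
  roc <- data.table::data.table(fpr = c(0, fpr), tpr = c(0, tpr),
                                threshold = c(Inf, thr))
  auroc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                  utils::tail(roc$tpr, -1)) / 2)
  precision <- cum_tp / (cum_tp + cum_fp)
  pr <- data.table::data.table(recall = c(0, tpr),
                               precision = c(precision[1], precision),
                               threshold = c(Inf, thr))
  auprc <- sum(diff(pr$recall) * (utils::head(pr$precision, -1) +
                                    utils::tail(pr$precision, -1)) / 2)
  list(roc = roc, auroc = auroc, pr = pr, auprc = auprc)
}

#' Confusion counts from a balanced test set at a top-k cut-off
#'
#' Scores each test site and takes "true kinase in the top k" as the
#' positive call for positives, and "target kinase in the top k" as a
#' false-positive call for negatives, mirroring the per-kinase evaluation
#' protocol.
#'
#' @param rank_fn function(site) -> ordered kinase ids.
#' @param test sites (vector or data.frame, positives and negatives).
#' @param labels logical labels for `test` rows.
#' @param kinase the kinase under evaluation.
#' @param k top-k cut-off.
#' @return named integer vector (tp, fp, tn, fn).
#' @export
topk_confusion <- function(rank_fn, test, labels, kinase, k = 10L) {
  calls <- vapply(seq_len(NROW(test)), function(i) {
    topk_hit(rank_fn(take_rows(test, i)), kinase, k)
  }, logical(1))
  c(tp = sum(calls & labels), fp = sum(calls & !labels),
    tn = sum(!calls & !labels), fn = sum(!calls & labels))
}
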