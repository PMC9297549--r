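## Evaluation for the imbalanced two-class problem: precision-recall
## analysis with SMAD3 as the positive class, confusion matrices at the
## prevalence-matched 0.75 cutoff, the ensemble-size ablation, and the
## GC-content class comparison.

as_binary_labels <- function(labels) {
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.numeric(labels))
  }
  encode_labels(labels)
}

#' Points of the precision-recall curve
#'
#' One point per distinct predicted probability, swept in decreasing
#' order; all items sharing a threshold enter together (ties grouped).
#' SMAD3 (label 1) is the positive class.
#'
#' @param probs predicted probabilities in \[0, 1\].
#' @param labels 0/1 or `"SMAD2"`/`"SMAD3"`.
#' @return data.frame with columns `threshold`, `recall`, `precision`.
#' @export
precision_recall_points <- function(probs, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(probs) == length(y))
  if (sum(y) == 0) stop("no positive labels")
  ord <- order(probs, decreasing = TRUE)
  p <- probs[ord]; y <- y[ord]
  thresholds <- unique(p)
  tp_cum <- cumsum(y)
  n_cum <- seq_along(y)
  # index of the last item at each distinct threshold
  last <- which(!duplicated(p, fromLast = TRUE))
  npos <- sum(y)
  data.frame(threshold = thresholds,
             recall = tp_cum[last] / npos,
             precision = tp_cum[last] / n_cum[last])
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise (non-interpolated) integral
#' \eqn{AP = \sum_k (R_k - R_{k-1}) P_k} over the threshold sweep.
#'
#' @inheritParams precision_recall_points
#' @return AP in \[0, 1\].
#' @export
average_precision <- function(probs, labels) {
  pr <- precision_recall_points(probs, labels)
  sum(diff(c(0, pr$recall)) * pr$precision)
}

#' Confusion matrix at a probability cutoff
#'
#' Probabilities at or above the threshold are called SMAD3, below it
#' SMAD2. The default 0.75 cutoff matches the SMAD3 prevalence in pooled
#' Smad2/3 peak sets, compensating for the class imbalance. Returns raw
#' counts and the row-normalized view (per-true-class recall).
#'
#' @inheritParams precision_recall_points
#' @param threshold decision cutoff in (0, 1).
#' @return list with `counts` (2x2, rows = true class), `normalized`
#'   (rows sum to 1), `recalls` (per-class), and `threshold`.
#' @export
confusion_at_threshold <- function(probs, labels, threshold = 0.75) {
  stopifnot(threshold > 0, threshold < 1)
  y <- as_binary_labels(labels)
  pred <- as.numeric(probs >= threshold)
  counts <- matrix(0L, 2, 2,
                   dimnames = list(true = SMAD_LEVELS, pred = SMAD_LEVELS))
  for (ty in 0:1) for (py in 0:1)
    counts[ty + 1, py + 1] <- sum(y == ty & pred == py)
  rs <- rowSums(counts)
  normalized <- sweep(counts, 1, pmax(rs, 1), "/")
  list(counts = counts, normalized = normalized,
       recalls = c(SMAD2 = normalized["SMAD2", "SMAD2"],
                   SMAD3 = normalized["SMAD3", "SMAD3"]),
       threshold = threshold)
}

#' Ensemble-size ablation
#'
#' For each ensemble size n = 1..M, evaluates the test AUPR of the
#' averaged prediction over every size-n subset of the M snapshots
#' (all \eqn{\binom{M}{n}} combinations) and reports the mean and
#' standard deviation. Larger ensembles should score higher and vary
#' less.
#'
#' @param ensemble a `smad_ensemble` with at most `max_m` snapshots.
#' @param x a `smad_onehot` test batch.
#' @param labels test labels (taken from `x$labels` when omitted).
#' @param max_m combinatorial guard on M (default 12).
#' @return data.frame with `n_models`, `n_subsets`, `mean_aupr`,
#'   `sd_aupr`.
#' @export
ablate_ensemble_size <- function(ensemble, x, labels = NULL, max_m = 12L) {
  if (is.null(labels)) labels <- x$labels
  y <- as_binary_labels(labels)
  P <- predict_snapshots(ensemble, x)   # cache member predictions once
  ablate_matrix(P, y, max_m = max_m)
}

# combinatorial core of the ablation, on a cached prediction matrix
# (one column per ensemble member)
ablate_matrix <- function(P, y, max_m = 12L) {
  M <- ncol(P)
  if (M > max_m)
    stop("M = ", M, " members: enumerating all subsets is infeasible; ",
         "sub-sample the ensemble first")
  rows <- lapply(seq_len(M), function(n) {
    subsets <- combn(M, n)
    auprs <- apply(subsets, 2, function(s)
      average_precision(rowMeans(P[, s, drop = FALSE]), y))
    data.frame(n_models = n, n_subsets = ncol(subsets),
               mean_aupr = mean(auprs),
               sd_aupr = if (length(auprs) > 1) sd(auprs) else 0)
  })
  do.call(rbind, rows)
}

#' Full evaluation report
#'
#' @inheritParams confusion_at_threshold
#' @return list of class `smad_eval` with `pr_curve`, `aupr`,
#'   `confusion`, `threshold`, `positive_class`.
#' @export
evaluate_predictions <- function(probs, labels, threshold = 0.75) {
  y <- as_binary_labels(labels)
  structure(list(pr_curve = precision_recall_points(probs, y),
                 aupr = average_precision(probs, y),
                 confusion = confusion_at_threshold(probs, y, threshold),
                 threshold = threshold,
                 positive_class = "SMAD3"),
            class = "smad_eval")
}

#' @export
print.smad_eval <- function(x, ...) {
  cat("<smad_eval> positive class ", x$positive_class, "\n", sep = "")
  cat(" AUPR:", round(x$aupr, 4), "\n")
  cat(" confusion at threshold ", x$threshold, " (rows = true class):\n",
      sep = "")
  print(x$confusion$counts)
  cat(" per-class recall: SMAD2 =",
      round(x$confusion$recalls["SMAD2"], 3), ", SMAD3 =",
      round(x$confusion$recalls["SMAD3"], 3), "\n")
  invisible(x)
}

#' GC-content comparison between SMAD2- and SMAD3-labeled sequences
#'
#' Per-sequence GC fractions (N excluded) compared with a two-sample
#' Welch t-test. Degenerate inputs (zero variance in both groups) are
#' reported with `t = 0`, `p = NaN` rather than an error.
#'
#' @param seqs DNAStringSet with `mcols()$label`, or character vector.
#' @param labels labels when `seqs` does not carry them.
#' @return list with `gc_mean_smad2`, `gc_mean_smad3`, `t_statistic`,
#'   `p_value`.
#' @export
gc_class_test <- function(seqs, labels = NULL) {
  if (is.null(labels) && methods::is(seqs, "DNAStringSet"))
    labels <- as.character(S4Vectors::mcols(seqs)$label)
  if (is.null(labels)) stop("labels are required")
  labels <- as.character(labels)
  gc <- gc_content(seqs)
  g2 <- gc[labels == "SMAD2"]; g3 <- gc[labels == "SMAD3"]
  if (length(g2) < 2 || length(g3) < 2)
    stop("both classes need at least 2 sequences")
  tt <- tryCatch(t.test(g2, g3, var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt)) {
    t_stat <- 0; p <- NaN   # constant data: no variance to test against
  } else {
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  list(gc_mean_smad2 = mean(g2), gc_mean_smad3 = mean(g3),
       t_statistic = t_stat, p_value = p)
}
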