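#' Repeated stratified k-fold plan
#'
#' Builds `R` independent stratified partitions of the documents into `k`
#' folds (the paper-style setting is k = 5 folds repeated in R = 10 sets).
#' Within each set the folds partition all documents, per-class fold sizes
#' differ by at most one, and each fold's positive fraction is within one
#' document of the corpus fraction. Sets use distinct seeds derived from
#' `seed`; a max-pairwise-Jaccard overlap diagnostic across sets
#' approximates the "orthogonality" of the repeats.
#'
#' @param labels binary 0/1 vector.
#' @param k folds per set (default 5).
#' @param R number of fold sets (default 10).
#' @param seed integer seed.
#' @return a `fold_plan`: `assignment` (n x R integer matrix of fold ids in
#'   1..k), `k`, `R`, `seed`, and `max_jaccard`.
#' @export
make_fold_plan <- function(labels, k = 5L, R = 10L, seed = 1L) {
  labels <- as.numeric(labels)
  stopifnot(all(labels %in% c(0, 1)), k >= 2L, R >= 1L)
  n <- length(labels)
  if (min(table(labels)) < k)
    stop("a class has fewer than k = ", k, " members; cannot stratify")
  assignment <- matrix(NA_integer_, n, R)
  for (r in seq_len(R)) {
    old <- withr_seed(seed + 1000L * r)
    for (cl in c(0, 1)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      assignment[idx, r] <- rep_len(seq_len(k), length(idx))
    }
    restore_seed(old)
  }
  structure(list(assignment = assignment, k = as.integer(k),
                 R = as.integer(R), seed = as.integer(seed),
                 labels = labels,
                 max_jaccard = fold_overlap(assignment, k)),
            class = "fold_plan")
}

# max pairwise Jaccard similarity between folds of different sets
fold_overlap <- function(assignment, k) {
  R <- ncol(assignment)
  if (R < 2L) return(NA_real_)
  best <- 0
  for (r in seq_len(R - 1L)) for (s in seq((r + 1L), R)) {
    for (a in seq_len(k)) {
      fa <- which(assignment[, r] == a)
      for (b in seq_len(k)) {
        fb <- which(assignment[, s] == b)
        j <- length(intersect(fa, fb)) / length(union(fa, fb))
        if (j > best) best <- j
      }
    }
  }
  best
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan>", length(x$labels), "documents,", x$k, "folds x", x$R,
      "sets; max cross-set fold Jaccard",
      format(x$max_jaccard, digits = 3), "\n")
  invisible(x)
}

#' Confusion counts at a probability threshold
#'
#' A document is predicted positive iff its score is `>= threshold`
#' (probabilities are "rounded up": a score exactly at the threshold is
#' class 1).
#'
#' @param scores probabilities in `[0, 1]`.
#' @param labels binary 0/1 truth.
#' @param threshold cutoff, default 0.5.
#' @return list with integers TP, FP, TN, FN.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  stopifnot(all(scores >= 0 & scores <= 1), all(labels %in% c(0, 1)))
  pred <- as.integer(scores >= threshold)
  list(TP = sum(pred == 1L & labels == 1),
       FP = sum(pred == 1L & labels == 0),
       TN = sum(pred == 0L & labels == 0),
       FN = sum(pred == 0L & labels == 1))
}

#' Classification metrics from confusion counts
#'
#' `ACC = (TP+TN)/total`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`, `precision = TP/(TP+FP)`, and
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any zero denominator yields `NA` (undefined), never a silent zero.
#'
#' @param c list with TP, FP, TN, FN (see [confusion()]).
#' @return list ACC, MCC, sensitivity, specificity, precision.
#' @export
metrics_from_confusion <- function(c) {
  TP <- c$TP; FP <- c$FP; TN <- c$TN; FN <- c$FN
  total <- TP + FP + TN + FN
  if (total == 0) stop("empty confusion table")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  denom <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  list(ACC = (TP + TN) / total,
       MCC = if (denom == 0) NA_real_ else (TP * TN - FP * FN) / denom,
       sensitivity = safe_div(TP, TP + FN),
       specificity = safe_div(TN, TN + FP),
       precision = safe_div(TP, TP + FP))
}

#' ROC curve and AUC
#'
#' AUC equals the trapezoidal area under the ROC curve over all distinct
#' score thresholds; tied positive/negative scores contribute 1/2
#' (rank-sum equivalence). 1.0 means perfect sorting of positives above
#' negatives, 0.5 no predictive performance.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary 0/1; both classes must be present.
#' @param curve also return the ROC points.
#' @return the AUC, or when `curve = TRUE` a list with `auc` and `roc`
#'   (data.frame threshold, sensitivity, specificity).
#' @export
roc_auc <- function(scores, labels, curve = FALSE) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  stopifnot(all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (!curve) return(auc)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(sensitivity = sum(pred & labels == 1) / n1,
      specificity = sum(!pred & labels == 0) / n0)
  }, numeric(2)))
  list(auc = auc,
       roc = data.frame(threshold = thr, sensitivity = pts[, 1],
                        specificity = pts[, 2]))
}

#' Root-mean-square error of probabilistic scores against 0/1 labels
#'
#' @param scores probabilities in `[0, 1]`.
#' @param labels binary 0/1.
#' @return `sqrt(mean((score - label)^2))`.
#' @export
rmse <- function(scores, labels) {
  if (length(scores) == 0L) stop("empty input")
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  stopifnot(all(scores >= 0 & scores <= 1))
  sqrt(mean((scores - labels)^2))
}

metric_row <- function(scores, labels, threshold = 0.5) {
  m <- metrics_from_confusion(confusion(scores, labels, threshold))
  c(ACC = m$ACC, AUC = roc_auc(scores, labels), MCC = m$MCC,
    RMSE = rmse(scores, labels), precision = m$precision,
    sensitivity = m$sensitivity, specificity = m$specificity)
}

#' Repeated stratified cross-validation of the boosted classifier
#'
#' For each fold set and fold, trains on the remaining k-1 folds and scores
#' the held-out fold; the seven metrics (ACC, AUC, MCC, RMSE, precision,
#' sensitivity, specificity) are computed per fold for training and
#' validation and aggregated by unweighted mean (with SD) across all
#' k x R folds.
#'
#' @param dtm a `dili_dtm` or numeric matrix.
#' @param labels binary response.
#' @param config a [booster_config()].
#' @param plan a [make_fold_plan()] plan covering the documents.
#' @param threshold classification cutoff for threshold-based metrics.
#' @return a `cv_result`: `scores` (n x R matrix of out-of-fold
#'   probabilities), `fold_metrics` (per set/fold/split data.frame), and
#'   `report` (a `metrics_report` with mean and sd per metric for training
#'   and validation).
#' @export
cross_validate <- function(dtm, labels, config = booster_config(), plan,
                           threshold = 0.5) {
  fm <- as_feature_matrix(dtm)
  y <- check_labels(labels, nrow(fm$X))
  if (nrow(plan$assignment) != length(y))
    stop("fold plan does not cover the documents")
  scores <- matrix(NA_real_, length(y), plan$R)
  rows <- list()
  for (r in seq_len(plan$R)) {
    for (f in seq_len(plan$k)) {
      hold <- plan$assignment[, r] == f
      fit <- tryCatch(
        train_booster(fm$X[!hold, , drop = FALSE], y[!hold], config),
        error = function(e) stop("set ", r, ", fold ", f, ": ",
                                 conditionMessage(e)))
      p_tr <- predict(fit, fm$X[!hold, , drop = FALSE])
      p_va <- predict(fit, fm$X[hold, , drop = FALSE])
      scores[hold, r] <- p_va
      rows[[length(rows) + 1L]] <-
        data.frame(set = r, fold = f, split = "training",
                   t(metric_row(p_tr, y[!hold], threshold)))
      rows[[length(rows) + 1L]] <-
        data.frame(set = r, fold = f, split = "validation",
                   t(metric_row(p_va, y[hold], threshold)))
    }
  }
  fold_metrics <- do.call(rbind, rows)
  structure(list(scores = scores, fold_metrics = fold_metrics,
                 report = metrics_report(fold_metrics), labels = y,
                 threshold = threshold),
            class = "cv_result")
}

metric_names <- c("ACC", "AUC", "MCC", "RMSE", "precision", "sensitivity",
                  "specificity")

metrics_report <- function(fold_metrics) {
  agg <- lapply(split(fold_metrics, fold_metrics$split), function(d) {
    data.frame(metric = metric_names,
               mean = vapply(metric_names,
                             function(m) mean(d[[m]], na.rm = TRUE),
                             numeric(1)),
               sd = vapply(metric_names,
                           function(m) stats::sd(d[[m]]), numeric(1)),
               row.names = NULL)
  })
  structure(agg, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  for (split in names(x)) {
    cat(split, ":\n", sep = "")
    d <- x[[split]]
    for (i in seq_len(nrow(d)))
      cat(sprintf("  %-12s %6.3f (sd %5.3f)\n", d$metric[i], d$mean[i],
                  d$sd[i]))
  }
  invisible(x)
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", nrow(x$scores), "documents,", ncol(x$scores),
      "fold sets\n")
  print(x$report)
  invisible(x)
}

#' Cost-sensitive threshold (profit-matrix) analysis
#'
#' Tabulates, at each probability threshold, how many documents are
#' predicted positive and the two misclassification counts: FN
#' (positive-class documents called negative - the clinically costlier
#' error) and FP (negative-class documents called positive). Raising the
#' threshold never decreases FN and never increases FP.
#'
#' @param scores probabilities in `[0, 1]`.
#' @param labels binary 0/1.
#' @param thresholds numeric thresholds in `[0, 1]` (default 0.25, 0.5,
#'   0.75).
#' @return a `profit_table` data.frame: threshold, predicted_positive,
#'   fn (DILI -> non-DILI), fp (non-DILI -> DILI).
#' @export
profit_analysis <- function(scores, labels, thresholds = c(0.25, 0.5, 0.75)) {
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]")
  thresholds <- sort(thresholds)
  rows <- lapply(thresholds, function(t) {
    c <- confusion(scores, labels, t)
    data.frame(threshold = t, predicted_positive = c$TP + c$FP,
               fn = c$FN, fp = c$FP)
  })
  structure(do.call(rbind, rows), class = c("profit_table", "data.frame"))
}

#' Probability-decile consistency with expert labels
#'
#' A document is consistent when its rounded-up classification
#' (probability >= 0.5 is class 1) agrees with the expert label, i.e. the
#' subtraction of rounded probability from the label is 0. Documents are
#' binned into the ten probability ranges [0,0.1), ..., [0.9,1], and the
#' consistency fraction is reported per bin and overall; well-calibrated
#' models show high consistency in the extreme bins and ~50% in the middle.
#'
#' @param scores probabilities in `[0, 1]`.
#' @param labels binary 0/1.
#' @return a `consistency_report`: `overall` fraction plus a `bins`
#'   data.frame (bin_lo, bin_hi, n, consistent, consistency; consistency NA
#'   for empty bins).
#' @export
consistency_report <- function(scores, labels) {
  stopifnot(length(scores) == length(labels),
            all(scores >= 0 & scores <= 1), all(labels %in% c(0, 1)))
  consistent <- as.integer(scores >= 0.5) == labels
  bin <- pmin(floor(scores * 10), 9) + 1L
  n <- tabulate(bin, nbins = 10L)
  ok <- vapply(1:10, function(b) sum(consistent[bin == b]), numeric(1))
  bins <- data.frame(bin_lo = (0:9) / 10, bin_hi = (1:10) / 10, n = n,
                     consistent = ok,
                     consistency = ifelse(n > 0, ok / n, NA_real_))
  structure(list(overall = mean(consistent), bins = bins),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("overall consistency: %.1f%%\n", 100 * x$overall))
  b <- x$bins
  for (i in seq_len(nrow(b)))
    cat(sprintf("  [%.1f, %.1f%s  n=%4d  %s\n", b$bin_lo[i], b$bin_hi[i],
                if (i == 10) "]" else ")", b$n[i],
                if (is.na(b$consistency[i])) "-"
                else sprintf("%5.1f%%", 100 * b$consistency[i])))
  invisible(x)
}
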