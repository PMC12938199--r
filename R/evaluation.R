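#' Confusion counts at a classification threshold
#'
#' @param scores Interaction probabilities.
#' @param labels Binary truth (1 interacting, 0 not).
#' @param threshold Classification threshold (default 0.5; a score
#'   strictly greater is called interacting).
#' @return Named integer vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  pred <- as.integer(scores > threshold)
  c(TP = sum(pred == 1L & labels == 1L),
    TN = sum(pred == 0L & labels == 0L),
    FP = sum(pred == 1L & labels == 0L),
    FN = sum(pred == 0L & labels == 1L))
}

#' The six confusion-matrix metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, F1 `2*precision*sensitivity/(precision+sensitivity)`,
#' MCC `(TP*TN - FP*FN)/sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))` and accuracy
#' `(TP+TN)/total`. A metric whose denominator is zero is reported as 0
#' and its name recorded in the `"degenerate"` attribute rather than
#' raising, so extreme-threshold reports do not crash.
#'
#' @param counts Named vector from [confusion_counts()].
#' @return Named numeric vector of the six metrics.
#' @export
confusion_metrics <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  if (tp + tn + fp + fn == 0) ppi_stop("all confusion counts are zero")
  degenerate <- character()
  safe <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); 0 } else num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  prec <- safe(tp, tp + fp, "precision")
  f1 <- safe(2 * prec * sens, prec + sens, "f1")
  mcc_den <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) { degenerate <- c(degenerate, "mcc"); 0 } else
    (tp * tn - fp * fn) / mcc_den
  out <- c(sensitivity = sens, specificity = spec, precision = prec,
           f1 = unname(f1), mcc = mcc,
           accuracy = (tp + tn) / (tp + tn + fp + fn))
  if (length(degenerate)) attr(out, "degenerate") <- degenerate
  out
}

#' ROC curve and AUC
#'
#' The AUC is the tie-corrected Mann-Whitney rank statistic (ties between
#' a positive and a negative score receive half credit); the curve is the
#' threshold sweep over the distinct scores, with tied scores grouped.
#'
#' @param scores Interaction probabilities.
#' @param labels Binary truth; both classes must be present.
#' @return List with `auc` and `curve` (data frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) ppi_stop("ROC requires both classes present")
  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1L), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0L), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr),
                      fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  list(auc = auc, curve = curve)
}

#' Precision-recall curve and AUPR
#'
#' Points are taken over the score-sorted sweep (tied scores grouped);
#' the area uses the step-wise rule
#' `sum_i (R_i - R_(i-1)) * P_i` with `R_0 = 0`.
#'
#' @param scores Interaction probabilities.
#' @param labels Binary truth; at least one positive required.
#' @return List with `aupr` and `curve` (data frame `threshold`,
#'   `recall`, `precision`).
#' @export
pr_aupr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L)
  if (n1 == 0L) ppi_stop("PR curve requires at least one positive")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1L), numeric(1))
  pp <- vapply(thr, function(t) sum(scores >= t), numeric(1))
  recall <- tp / n1
  precision <- tp / pp
  aupr <- sum(diff(c(0, recall)) * precision)
  list(aupr = aupr,
       curve = data.frame(threshold = thr, recall = recall,
                          precision = precision))
}

#' Precision among the top-u scored pairs
#'
#' Ties are broken by stable input order.
#'
#' @param scores Interaction probabilities.
#' @param labels Binary truth.
#' @param u Number of top predictions (the network evaluations use 100,
#'   200, 300).
#' @return Fraction of true positives among the `u` highest-scored pairs.
#' @export
top_u_precision <- function(scores, labels, u) {
  if (length(scores) < u) {
    ppi_stop("top-u precision needs at least u = %d samples (got %d)",
             u, length(scores))
  }
  ord <- order(-scores)         # radix sort: stable for ties
  mean(labels[ord[seq_len(u)]] == 1L)
}

#' Thresholded network edge prediction
#'
#' In `"interaction"` mode, pairs with score strictly above the threshold
#' are kept as predicted interacting edges (the network application uses
#' 0.98); in `"non_interaction"` mode, pairs with score strictly below the
#' threshold are kept as predicted non-interacting edges (0.01).
#'
#' @param scores Ensemble interaction probabilities, aligned with `pairs`.
#' @param pairs Pair table (`id_a`, `id_b`).
#' @param threshold Decision threshold.
#' @param mode `"interaction"` or `"non_interaction"`.
#' @return Edge table `id_a`, `id_b`, `score`.
#' @export
network_predict <- function(scores, pairs, threshold = 0.98,
                            mode = c("interaction", "non_interaction")) {
  mode <- match.arg(mode)
  stopifnot(length(scores) == nrow(pairs))
  keep <- if (mode == "interaction") scores > threshold else scores < threshold
  data.frame(id_a = pairs$id_a[keep], id_b = pairs$id_b[keep],
             score = scores[keep], stringsAsFactors = FALSE)
}

#' Full evaluation report for an ensemble
#'
#' Computes the six confusion metrics for the averaged ensemble and for
#' each member (reported as mean, standard deviation and variance across
#' members), plus ROC-AUC and AUPR of the ensemble scores.
#'
#' @param probs Member probability matrix from [member_probs()] (or a
#'   plain score vector, treated as a single member).
#' @param labels Binary truth.
#' @param threshold Classification threshold (default 0.5).
#' @return List with `ensemble` metrics, `member_mean`, `member_sd`,
#'   `member_var`, `auc`, `aupr` and the confusion `counts`.
#' @export
evaluation_report <- function(probs, labels, threshold = 0.5) {
  if (!is.matrix(probs)) probs <- matrix(probs, ncol = 1L)
  ens <- rowMeans(probs)
  per_member <- apply(probs, 2L, function(p)
    confusion_metrics(confusion_counts(p, labels, threshold)))
  list(ensemble = confusion_metrics(confusion_counts(ens, labels, threshold)),
       member_mean = rowMeans(per_member),
       member_sd = apply(per_member, 1L, stats::sd),
       member_var = apply(per_member, 1L, stats::var),
       auc = roc_auc(ens, labels)$auc,
       aupr = pr_aupr(ens, labels)$aupr,
       counts = confusion_counts(ens, labels, threshold))
}
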