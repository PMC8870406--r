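# Evaluation: IoU matching of predictions to ground truth, the three-level
# confusion matrices (gland classification, gland detection with a
# stroma/background pseudo-class, core diagnosis), per-class report tables,
# the detection-confidence sweep and ROC/AUC.

#' Mask intersection-over-union
#'
#' @param a,b logical matrices of identical shape.
#' @return IoU in `[0, 1]` (0 when both masks are empty).
#' @export
mask_iou <- function(a, b) {
  assert_that(all(dim(a) == dim(b)), "masks must share one shape", format_error)
  inter <- sum(a & b)
  if (inter == 0L) return(0)
  inter / sum(a | b)
}

#' Match predicted to ground-truth instances
#'
#' Greedy one-to-one matching: predictions are visited in order of
#' descending score and each takes the unmatched ground-truth instance of
#' highest mask IoU, provided that IoU reaches `iou_min`. Because the greedy
#' order is by score, the matches of the top-scoring predictions do not
#' depend on lower-scoring ones — the basis of threshold nestedness.
#'
#' @param preds list of [gland_instance()] predictions.
#' @param truths list of [gland_instance()] ground truth.
#' @param iou_min minimum IoU for a valid match (default 0.5, the instance-
#'   detection convention).
#' @return an object of class `instance_matching`: `pairs` (data.frame
#'   `pred`, `truth`, `iou`), `unmatched_preds`, `unmatched_truths`,
#'   `iou_min`.
#' @export
match_instances <- function(preds, truths, iou_min = 0.5) {
  if (length(preds) && length(truths)) {
    assert_that(all(dim(preds[[1L]]$mask) == dim(truths[[1L]]$mask)),
                "prediction and truth masks must share the image shape",
                format_error)
  }
  ord <- order(vapply(preds, `[[`, numeric(1L), "score"), decreasing = TRUE)
  taken <- logical(length(truths))
  pairs <- data.frame(pred = integer(0), truth = integer(0), iou = numeric(0))
  for (i in ord) {
    if (!length(truths)) break
    # bbox prefilter: IoU can only be positive when boxes intersect
    cand <- which(!taken)
    cand <- cand[vapply(cand, function(j)
      box_iou(preds[[i]]$bbox, truths[[j]]$bbox) > 0, logical(1L))]
    if (!length(cand)) next
    ious <- vapply(cand, function(j) mask_iou(preds[[i]]$mask, truths[[j]]$mask),
                   numeric(1L))
    best <- which.max(ious)
    if (ious[best] >= iou_min) {
      j <- cand[best]
      taken[j] <- TRUE
      pairs <- rbind(pairs, data.frame(pred = i, truth = j, iou = ious[best]))
    }
  }
  structure(list(pairs = pairs,
                 unmatched_preds = setdiff(seq_along(preds), pairs$pred),
                 unmatched_truths = which(!taken),
                 iou_min = iou_min),
            class = "instance_matching")
}

#' Build a labeled confusion matrix
#'
#' @param actual,predicted character vectors of equal length.
#' @param labels class label order (rows = actual, columns = predicted).
#' @return integer matrix with `dimnames` `(actual, predicted)`.
#' @export
confusion_matrix <- function(actual, predicted, labels) {
  assert_that(length(actual) == length(predicted),
              "actual and predicted must have equal length", format_error)
  m <- table(factor(actual, levels = labels), factor(predicted, levels = labels))
  m <- matrix(as.integer(m), length(labels), length(labels),
              dimnames = list(actual = labels, predicted = labels))
  m
}

#' Detection-level confusion matrix with a stroma/background pseudo-class
#'
#' Matched pairs count as (truth class, predicted class); unmatched ground
#' truths count against the stroma column (missed); unmatched predictions
#' count in the stroma row (false detections on non-gland tissue). Stroma is
#' not a trained class — it is the unmatched territory of the evaluation.
#'
#' @param matchings an `instance_matching` or list of them (one per core).
#' @param preds,truths the prediction/truth lists matching `matchings`
#'   (lists of lists when `matchings` is a list).
#' @param classes gland classes (default cancer, normal).
#' @param background pseudo-class name (default `"stroma"`).
#' @return integer confusion matrix over `c(classes, background)`.
#' @export
detection_confusion <- function(matchings, preds, truths,
                                classes = c("cancer", "normal"),
                                background = "stroma") {
  if (inherits(matchings, "instance_matching")) {
    matchings <- list(matchings); preds <- list(preds); truths <- list(truths)
  }
  labels <- c(classes, background)
  acc <- matrix(0L, length(labels), length(labels),
                dimnames = list(actual = labels, predicted = labels))
  for (k in seq_along(matchings)) {
    m <- matchings[[k]]; p <- preds[[k]]; t <- truths[[k]]
    for (r in seq_len(nrow(m$pairs))) {
      a <- t[[m$pairs$truth[r]]]$class_label
      b <- p[[m$pairs$pred[r]]]$class_label
      acc[a, b] <- acc[a, b] + 1L
    }
    for (j in m$unmatched_truths) {
      acc[t[[j]]$class_label, background] <- acc[t[[j]]$class_label, background] + 1L
    }
    for (i in m$unmatched_preds) {
      acc[background, p[[i]]$class_label] <- acc[background, p[[i]]$class_label] + 1L
    }
  }
  acc
}

#' Classification confusion matrix from a detection matrix
#'
#' Restricts the detection matrix to detected glands by dropping the
#' background row and column: what remains is classification performance on
#' the glands that were found.
#'
#' @param cm detection confusion matrix from [detection_confusion()].
#' @param background pseudo-class name to drop.
#' @return confusion matrix over the gland classes only.
#' @export
classification_from_detection <- function(cm, background = "stroma") {
  keep <- setdiff(rownames(cm), background)
  cm[keep, keep, drop = FALSE]
}

#' Per-class precision/recall/F1 report
#'
#' For each class: precision = diagonal / column sum (0 for an empty
#' column), recall = diagonal / row sum, F1 their harmonic mean (0 when both
#' are 0), support = row sum. Overall accuracy = trace / total; macro
#' average = unweighted class mean; weighted average = support-weighted
#' class mean. All metrics are kept at full precision; rounding is applied
#' only by the print method.
#'
#' @param cm confusion matrix (rows = actual, columns = predicted).
#' @return an object of class `screening_report`: data.frame `per_class`
#'   plus `accuracy`, `macro_avg`, `weighted_avg`, `total`.
#' @export
report <- function(cm) {
  assert_that(is.matrix(cm) && nrow(cm) == ncol(cm) && nrow(cm) >= 1L &&
                sum(cm) > 0, "confusion matrix must be non-empty and square")
  assert_that(all(cm >= 0), "confusion counts must be non-negative")
  classes <- rownames(cm)
  diagc <- diag(cm)
  colsum <- colSums(cm)
  rowsum <- rowSums(cm)
  precision <- ifelse(colsum > 0, diagc / colsum, 0)
  recall <- ifelse(rowsum > 0, diagc / rowsum, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(class = classes, precision = precision, recall = recall,
                          f1 = f1, support = as.integer(rowsum),
                          row.names = NULL, stringsAsFactors = FALSE)
  total <- sum(cm)
  wavg <- function(x) sum(x * rowsum) / total
  structure(list(
    per_class = per_class,
    accuracy = sum(diagc) / total,
    macro_avg = c(precision = mean(precision), recall = mean(recall), f1 = mean(f1)),
    weighted_avg = c(precision = wavg(precision), recall = wavg(recall),
                     f1 = wavg(f1)),
    total = as.integer(total)),
    class = "screening_report")
}

#' @export
print.screening_report <- function(x, digits = 2, ...) {
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  cat(sprintf("%-14s %9s %9s %9s %9s\n", "", "Precision", "Recall", "F1-Score",
              "Support"))
  for (i in seq_len(nrow(x$per_class))) {
    p <- x$per_class[i, ]
    cat(sprintf("%-14s %9s %9s %9s %9d\n", p$class, fmt(p$precision),
                fmt(p$recall), fmt(p$f1), p$support))
  }
  cat(sprintf("%-14s %9s %9s %9s %9d\n", "Accuracy", "", "", fmt(x$accuracy),
              x$total))
  cat(sprintf("%-14s %9s %9s %9s %9d\n", "Macro Avg", fmt(x$macro_avg["precision"]),
              fmt(x$macro_avg["recall"]), fmt(x$macro_avg["f1"]), x$total))
  cat(sprintf("%-14s %9s %9s %9s %9d\n", "Weighted Avg",
              fmt(x$weighted_avg["precision"]), fmt(x$weighted_avg["recall"]),
              fmt(x$weighted_avg["f1"]), x$total))
  invisible(x)
}

#' Flatten a report to a data.frame (Tables layout)
#'
#' @param x a `screening_report`.
#' @param row.names,optional,... standard [as.data.frame()] arguments
#'   (unused).
#' @return data.frame with one row per class plus Accuracy / Macro Avg /
#'   Weighted Avg rows.
#' @export
as.data.frame.screening_report <- function(x, row.names = NULL, optional = FALSE,
                                           ...) {
  pc <- x$per_class
  rbind(
    data.frame(row = pc$class, precision = pc$precision, recall = pc$recall,
               f1 = pc$f1, support = pc$support, stringsAsFactors = FALSE),
    data.frame(row = "Accuracy", precision = NA, recall = NA, f1 = x$accuracy,
               support = x$total),
    data.frame(row = "Macro Avg", precision = x$macro_avg[["precision"]],
               recall = x$macro_avg[["recall"]], f1 = x$macro_avg[["f1"]],
               support = x$total),
    data.frame(row = "Weighted Avg", precision = x$weighted_avg[["precision"]],
               recall = x$weighted_avg[["recall"]], f1 = x$weighted_avg[["f1"]],
               support = x$total))
}

#' Detection-confidence sweep
#'
#' Runs the detector once at the most permissive threshold and filters by
#' score for every requested threshold (scores are fixed by the model, so
#' this is exactly detection at each threshold), then reports the fraction
#' of ground-truth glands matched at `iou_min`. Fractions are non-increasing
#' in the threshold because higher-threshold detections are a prefix of
#' lower-threshold ones.
#'
#' @param model detector state accepted by [detect()].
#' @param cores list of phase maps.
#' @param truths list of [core_ground_truth()] aligned with `cores`.
#' @param thresholds detection-confidence thresholds (default 0.70, 0.80,
#'   0.90).
#' @param iou_min match criterion.
#' @return data.frame with `threshold`, `detected`, `total`,
#'   `detected_fraction`, ordered by ascending threshold.
#' @export
confidence_sweep <- function(model, cores, truths,
                             thresholds = c(0.70, 0.80, 0.90), iou_min = 0.5) {
  assert_that(all(thresholds > 0 & thresholds <= 1), "thresholds must be in (0, 1]")
  thresholds <- sort(thresholds)
  base <- lapply(cores, function(c) detect(c, model, min(thresholds)))
  total <- sum(vapply(truths, function(t) length(t$instances), integer(1L)))
  rows <- lapply(thresholds, function(th) {
    detected <- 0L
    for (k in seq_along(cores)) {
      keep <- base[[k]][vapply(base[[k]], `[[`, numeric(1L), "score") >= th]
      m <- match_instances(keep, truths[[k]]$instances, iou_min = iou_min)
      detected <- detected + nrow(m$pairs)
    }
    data.frame(threshold = th, detected = detected, total = total,
               detected_fraction = if (total > 0L) detected / total else 0)
  })
  do.call(rbind, rows)
}

#' Trapezoidal ROC AUC
#'
#' Area under the ROC curve from a full threshold sweep with trapezoidal
#' integration; tied scores are grouped at a single threshold, which is
#' equivalent to the midrank (half-weight ties) convention and hence to the
#' Mann-Whitney pairwise concordance probability.
#'
#' @param scores numeric vector of classifier scores (higher = positive).
#' @param labels logical or 0/1 vector; `TRUE`/1 marks the positive class.
#' @return scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  assert_that(length(scores) == length(labels) && length(scores) > 0L,
              "scores and labels must be equal-length and non-empty")
  assert_that(any(labels) && any(!labels),
              "both classes must be present to compute an AUC")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores at one threshold
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp <- c(0, cumsum(tapply(as.integer(y), grp, sum)))
  fp <- c(0, cumsum(tapply(as.integer(!y), grp, sum)))
  tpr <- tp / sum(y)
  fpr <- fp / sum(!y)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
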