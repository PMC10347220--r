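# Training objective and evaluation metrics.

.ceRow <- function(z, y) {
  # cross-entropy of one logit vector against integer label y in {0, 1}
  zmax <- max(z)
  (zmax + log(sum(exp(z - zmax)))) - z[y + 1L]
}

#' Joint diagnosis + select loss
#'
#' Total loss = cross-entropy of the diagnosis logits against the scan
#' label, plus, for every fusion stage, the cross-entropy of each
#' (selected) node's score vector against the same scan label.
#'
#' @param diagLogits length-2 diagnosis logits.
#' @param selectLogits list over fusion stages; each element an `m x 2`
#'   matrix of per-node score logits (the selected nodes' rows under the
#'   default mode).
#' @param y scan label, 0 or 1.
#' @param reduce `"sum"` (default, as the loss is written) or `"mean"`
#'   over nodes within each stage.
#' @return list with `diagnosis`, `select` (one value per stage) and
#'   `total`.
#' @examples
#' totalLoss(c(0, 0), list(matrix(0, 2, 2), matrix(0, 1, 2)), 1L)
#' @export
totalLoss <- function(diagLogits, selectLogits = list(), y,
                      reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  if (!y %in% c(0L, 1L)) stop("label must be 0 or 1")
  if (length(diagLogits) != 2L) stop("diagnosis logits must have length 2")
  dl <- .ceRow(as.numeric(diagLogits), as.integer(y))
  sel <- vapply(selectLogits, function(m) {
    m <- rbind(m)
    v <- vapply(seq_len(nrow(m)), function(i)
      .ceRow(as.numeric(m[i, ]), as.integer(y)), 0)
    if (reduce == "sum") sum(v) else mean(v)
  }, 0)
  list(diagnosis = dl, select = sel, total = dl + sum(sel))
}

#' Confusion counts at the argmax operating point
#'
#' @param predicted predicted class per scan (0/1).
#' @param labels true labels (0/1).
#' @return named integer vector `tp, tn, fp, fn`.
#' @export
confusionCounts <- function(predicted, labels) {
  c(tp = sum(predicted == 1L & labels == 1L),
    tn = sum(predicted == 0L & labels == 0L),
    fp = sum(predicted == 1L & labels == 0L),
    fn = sum(predicted == 0L & labels == 1L))
}

#' Classification accuracy from confusion counts
#'
#' @param counts named vector or list with `tp, tn, fp, fn`.
#' @return `(tp + tn) / (tp + tn + fp + fn)`.
#' @export
accuracy <- function(counts) {
  counts <- unlist(counts)[c("tp", "tn", "fp", "fn")]
  if (any(counts < 0)) stop("negative counts")
  tot <- sum(counts)
  if (tot == 0) stop("no observations")
  unname((counts["tp"] + counts["tn"]) / tot)
}

#' Area under the ROC curve
#'
#' Computed as the tie-corrected Mann-Whitney statistic (equal to the
#' trapezoidal area under the TPR-vs-FPR curve over all thresholds).
#'
#' @param scores positive-class score per scan.
#' @param labels true labels (0/1); both classes must be present.
#' @return AUC in `[0, 1]`.
#' @examples
#' rocAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    stop("AUC is undefined: both classes must be present in the labels")
  r <- rank(scores)
  unname((sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg))
}

#' Throughput in images per second
#'
#' @param nImages total number of processed images.
#' @param batchTimeSeconds total processing time of one batch in seconds.
#' @param batchSize batch size.
#' @return `nImages / (batchTimeSeconds * batchSize)`.
#' @export
throughput <- function(nImages, batchTimeSeconds, batchSize) {
  if (batchTimeSeconds <= 0) stop("batch time must be positive")
  nImages / (batchTimeSeconds * batchSize)
}

#' Learning-rate schedule: linear warmup then cosine decay
#'
#' The learning rate rises linearly to `lrMax` over the first
#' `warmupEpochs` epochs (reaching `lrMax` at the end of the warmup) and
#' then follows a half-cosine from `lrMax` down to `lrMin` at the final
#' epoch.
#'
#' @param epoch epoch number (1-based; vectorized).
#' @param totalEpochs total number of training epochs.
#' @param warmupEpochs warmup length in epochs.
#' @param lrMax peak learning rate.
#' @param lrMin final learning rate.
#' @return learning rate(s) for the given epoch(s).
#' @examples
#' lrSchedule(5, 200)    # 1e-4
#' lrSchedule(200, 200)  # 1e-6
#' @export
lrSchedule <- function(epoch, totalEpochs, warmupEpochs = 5L,
                       lrMax = 1e-4, lrMin = 1e-6) {
  stopifnot(totalEpochs >= warmupEpochs)
  ifelse(epoch <= warmupEpochs,
         lrMax * epoch / warmupEpochs,
         lrMin + 0.5 * (lrMax - lrMin) *
           (1 + cos(pi * (epoch - warmupEpochs) /
                      max(1L, totalEpochs - warmupEpochs))))
}
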