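# Whole-model forward pass and the training loss graph.
#
# The diagnosis head is a linear 2-way classifier on the concatenation of
# the fused graph feature f_out with the final text feature: the image
# stream is never modified by the indicators (one-way flow), so the
# indicator information reaches the prediction only through the text
# feature the USA blocks have been updating.

.headNodes <- function(fout, ft, pg, dropout = 0) {
  z <- adCbind(list(fout, ft))
  if (dropout > 0) {
    # inverted dropout on the head input (training only)
    keep <- (stats::runif(ncol(z$val)) >= dropout) / (1 - dropout)
    z <- adConstMul(z, matrix(keep, 1L))
  }
  adLinear(z, pg("head.w"), pg("head.b"))
}

# Full forward on tape; returns nodes + bookkeeping.
.hgtNodes <- function(pg, cfg, slices, ind, sliceIdx, dropout = 0) {
  bb <- .backboneForwardNodes(pg, cfg, slices, ind)
  fu <- .fusionNodes(bb$F1, sliceIdx, pg, cfg)
  logits <- .headNodes(fu$fOut, bb$ft, pg, dropout)
  list(logits = logits, backbone = bb, fusion = fu)
}

#' Forward pass of the full model on one scan
#'
#' Runs the sampled slice stack and the indicator vector through the
#' image backbone, the USA blocks and the GCN fusion head.
#'
#' @param model an [HGTModel].
#' @param slices `(h, w, n)` array of the already-sampled slices, values
#'   in `[0, 1]`, `h = w =` the configured image size.
#' @param ind indicator vector of length 14.
#' @param sliceIdx original (0-based) slice indices of the sampled slices;
#'   defaults to `0:(n-1)`.
#' @return list with `logits` (length 2), `prob` (positive-class softmax
#'   probability), `fOut`, `textFeature`, `sliceFeatures` (the per-slice
#'   features entering fusion), `stagePooled` (per-stage pooled image
#'   features, for one-way-flow audits) and `fusion` (node counts, kept
#'   positions and select logits per stage).
#' @export
hgtForward <- function(model, slices, ind, sliceIdx = NULL) {
  cfg <- modelConfig(model)
  d <- dim(slices)
  if (d[1] != cfg$imageSize || d[2] != cfg$imageSize)
    stop(sprintf("slices must be %dx%d", cfg$imageSize, cfg$imageSize))
  if (is.null(sliceIdx)) sliceIdx <- seq_len(d[3]) - 1L
  leaves <- adParams(modelParams(model))
  pg <- function(nm) {
    nd <- leaves[[nm]]
    if (is.null(nd)) stop(sprintf("missing parameter '%s'", nm))
    nd
  }
  out <- .hgtNodes(pg, cfg, slices, ind, sliceIdx)
  z <- as.numeric(out$logits$val)
  p <- exp(z - max(z))
  p <- p / sum(p)
  list(logits = z,
       prob = p[2],
       fOut = as.numeric(out$fusion$fOut$val),
       textFeature = as.numeric(out$backbone$ft$val),
       sliceFeatures = out$backbone$F1$val,
       stagePooled = out$backbone$stagePooled,
       fusion = list(nodeCounts = out$fusion$counts,
                     positions = out$fusion$sels,
                     selectLogits = lapply(out$fusion$phis, `[[`, "val")))
}

# Loss graph for one scan (tape must be active; leaves shared per batch).
.scanLossNodes <- function(pg, cfg, slices, ind, sliceIdx, y, dropout = 0) {
  out <- .hgtNodes(pg, cfg, slices, ind, sliceIdx, dropout)
  diag_ <- adCrossEntropy(out$logits, y)
  total <- diag_
  selv <- numeric(length(out$fusion$phis))
  for (l in seq_along(out$fusion$phis)) {
    phi <- out$fusion$phis[[l]]
    rows <- if (cfg$selectLoss == "selected") out$fusion$sels[[l]]
            else seq_len(nrow(phi$val))
    ce <- adCrossEntropy(adGather(phi, rows), rep(y, length(rows)))
    if (cfg$selectReduce == "mean") ce <- adScale(ce, 1 / length(rows))
    selv[l] <- ce$val
    total <- adAdd(total, ce)
  }
  list(total = total, diagnosis = diag_$val, select = selv,
       logits = as.numeric(out$logits$val))
}

#' Predict a scan end to end
#'
#' Samples slice indices with the configured strategy (a fixed seed gives
#' the reproducible evaluation-time draw), optionally zeroes one modality
#' for modality-isolation experiments, and runs [hgtForward()].
#'
#' @param model an [HGTModel].
#' @param scan a [CTScan].
#' @param seed integer seed for the slice draw.
#' @param zeroIndicators replace the indicator vector by zeros.
#' @param zeroImages replace all sampled slices by zeros.
#' @return the [hgtForward()] result plus `sliceIdx`.
#' @export
hgtPredict <- function(model, scan, seed = NULL, zeroIndicators = FALSE,
                       zeroImages = FALSE) {
  cfg <- modelConfig(model)
  idx <- sampleSlices(nSlices(scan), cfg$nSamples, cfg$sampling, seed = seed)
  sl <- scan@slices[, , idx + 1L, drop = FALSE]
  if (zeroImages) sl[] <- 0
  ind <- indicators(scan)
  if (zeroIndicators) ind[] <- 0
  out <- hgtForward(model, sl, ind, sliceIdx = idx)
  out$sliceIdx <- idx
  out
}
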