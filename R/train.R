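# Training loop: AdamW with linear warmup + cosine decay, per-epoch
# re-drawn slice samples, horizontal-flip and small-rotation augmentation.

.augmentSlices <- function(sl, maxRotation = 10, noiseSd = 0) {
  h <- dim(sl)[1]
  if (stats::runif(1L) < 0.5) sl <- sl[, dim(sl)[2]:1, , drop = FALSE]
  angle <- stats::runif(1L, -maxRotation, maxRotation)
  for (k in seq_len(dim(sl)[3])) {
    rot <- EBImage::rotate(sl[, , k], angle, output.dim = c(h, h),
                           bg.col = 0)
    sl[, , k] <- EBImage::imageData(rot)
  }
  if (noiseSd > 0) sl <- sl + stats::rnorm(length(sl), sd = noiseSd)
  pmin(pmax(sl, 0), 1)
}

.checkTrainInputs <- function(model, data) {
  cfg <- modelConfig(model)
  for (i in seq_len(length(data))) {
    scan <- data[[i]]
    d <- dim(scan@slices)
    if (d[1] != cfg$imageSize || d[2] != cfg$imageSize)
      stop(sprintf("scan '%s' has %dx%d slices; model expects %dx%d",
                   scanId(scan), d[1], d[2], cfg$imageSize, cfg$imageSize))
    if (nSlices(scan) < cfg$nSamples)
      stop(sprintf("scan '%s' has %d slices, fewer than the %d to sample",
                   scanId(scan), nSlices(scan), cfg$nSamples))
  }
  labs <- vapply(seq_len(length(data)), function(i) scanLabel(data[[i]]), 0L)
  if (length(unique(labs)) < 2L)
    warning("training split contains a single class")
  invisible(NULL)
}

#' Train the multimodal fusion model
#'
#' AdamW (decoupled weight decay) with a learning rate warmed up linearly
#' over the first `warmupEpochs` epochs and decayed to `lrMin` on a cosine
#' schedule ([lrSchedule()]).  Each epoch re-draws the per-scan slice
#' sample with the configured strategy, and applies horizontal-flip and
#' small-rotation augmentation.  Fully seeded: identical seeds give
#' identical runs.
#'
#' @param model an [HGTModel] (its parameters are the starting point).
#' @param data training [ScanDataset].
#' @param epochs number of epochs.
#' @param batchSize scans per optimizer step.
#' @param lrMax,lrMin,warmupEpochs learning-rate schedule, see
#'   [lrSchedule()].
#' @param weightDecay AdamW decoupled weight decay.
#' @param clipNorm global gradient-norm clipping threshold (`Inf`
#'   disables).
#' @param augment logical; apply flip/rotation/noise augmentation.
#' @param maxRotation rotation bound in degrees.
#' @param noiseSd standard deviation of additive pixel-noise augmentation
#'   (applied when `augment = TRUE`; 0 disables).
#' @param indicatorJitter standard deviation of Gaussian jitter added to
#'   the continuous indicator channels during training (clipped back to
#'   `[0, 1]`; 0 disables).
#' @param flagFlipProb probability of flipping each binary indicator
#'   channel during training (0 disables).
#' @param headDropout dropout probability on the diagnosis-head input
#'   during training.
#' @param seed integer seed for sampling, augmentation and scan order.
#' @param evalData optional [ScanDataset] evaluated after every
#'   `evalEvery` epochs and at the end.
#' @param evalEvery evaluation period in epochs (0 = only at the end).
#' @param logFile optional CSV path; one row per epoch (epoch, lr, loss,
#'   diagnosis and select components, evaluation metrics when computed).
#' @param checkpointDir optional directory for per-evaluation model
#'   checkpoints (RDS).
#' @param verbose print per-epoch progress.
#' @return list with `model` (trained), `log` (data frame) and `eval`
#'   (final [evaluateModel()] report, if `evalData` was given).
#' @export
trainHGT <- function(model, data, epochs = 30L, batchSize = 2L,
                     lrMax = 1e-4, lrMin = 1e-6, warmupEpochs = 5L,
                     weightDecay = 0.01, clipNorm = 1.0, augment = TRUE,
                     maxRotation = 10, noiseSd = 0.03, indicatorJitter = 0.1,
                     flagFlipProb = 0.05, headDropout = 0.1,
                     seed = 1L, evalData = NULL, evalEvery = 0L,
                     logFile = NULL, checkpointDir = NULL, verbose = FALSE) {
  .checkTrainInputs(model, data)
  warmupEpochs <- min(warmupEpochs, epochs)
  cfg <- modelConfig(model)
  params <- modelParams(model)
  state <- adamwInit(params)
  nScans <- length(data)
  log <- list()
  .withSeed(seed, {
    for (epoch in seq_len(epochs)) {
      lr <- lrSchedule(epoch, epochs, warmupEpochs, lrMax, lrMin)
      ord <- sample.int(nScans)
      epochLoss <- epochDiag <- epochSel <- 0
      nBatches <- 0L
      for (b0 in seq(1L, nScans, by = batchSize)) {
        batch <- ord[b0:min(b0 + batchSize - 1L, nScans)]
        adTapeStart()
        leaves <- adParams(params)
        pg <- function(nm) leaves[[nm]]
        total <- NULL
        for (si in batch) {
          scan <- data[[si]]
          idx <- sampleSlices(nSlices(scan), cfg$nSamples, cfg$sampling)
          sl <- scan@slices[, , idx + 1L, drop = FALSE]
          ind <- indicators(scan)
          if (augment) {
            sl <- .augmentSlices(sl, maxRotation, noiseSd)
            binary <- ind %in% c(0, 1)
            if (indicatorJitter > 0) {
              jit <- stats::rnorm(length(ind), sd = indicatorJitter)
              ind[!binary] <- pmin(pmax(ind[!binary] + jit[!binary], 0), 1)
            }
            if (flagFlipProb > 0) {
              flip <- binary & stats::runif(length(ind)) < flagFlipProb
              ind[flip] <- 1 - ind[flip]
            }
          }
          ln <- .scanLossNodes(pg, cfg, sl, ind, idx, scanLabel(scan),
                               dropout = headDropout)
          epochDiag <- epochDiag + ln$diagnosis
          epochSel <- epochSel + sum(ln$select)
          total <- if (is.null(total)) ln$total else adAdd(total, ln$total)
        }
        total <- adScale(total, 1 / length(batch))
        adBackward(total)
        grads <- adGrads(leaves)
        adTapeStop()
        st <- adamwStep(params, grads, state, lr,
                        weightDecay = weightDecay, clipNorm = clipNorm)
        params <- st$params
        state <- st$state
        epochLoss <- epochLoss + total$val[1]
        nBatches <- nBatches + 1L
      }
      row <- data.frame(epoch = epoch, lr = lr,
                        loss = epochLoss / nBatches,
                        diagnosisLoss = epochDiag / nScans,
                        selectLoss = epochSel / nScans,
                        evalAcc = NA_real_, evalAuc = NA_real_)
      doEval <- !is.null(evalData) &&
        ((evalEvery > 0L && epoch %% evalEvery == 0L) || epoch == epochs)
      if (doEval) {
        m <- new("HGTModel", params = params, config = cfg)
        ev <- evaluateModel(m, evalData, seed = seed)
        row$evalAcc <- ev$acc
        row$evalAuc <- ev$auc
        if (!is.null(checkpointDir)) {
          dir.create(checkpointDir, recursive = TRUE, showWarnings = FALSE)
          saveRDS(m, file.path(checkpointDir,
                               sprintf("model_epoch%03d.rds", epoch)))
        }
      }
      log[[epoch]] <- row
      if (!is.null(logFile))
        utils::write.csv(do.call(rbind, log), logFile, row.names = FALSE)
      if (verbose)
        message(sprintf("epoch %3d  lr %.2e  loss %.4f%s", epoch, lr,
                        row$loss,
                        if (is.na(row$evalAuc)) ""
                        else sprintf("  eval ACC %.3f AUC %.3f",
                                     row$evalAcc, row$evalAuc)))
    }
  })
  model <- new("HGTModel", params = params, config = cfg)
  out <- list(model = model, log = do.call(rbind, log))
  if (!is.null(evalData)) out$eval <- evaluateModel(model, evalData,
                                                    seed = seed)
  out
}

#' Evaluate a model on a scan dataset
#'
#' Uses a fixed per-scan slice-sampling seed (reproducible evaluation),
#' classifies each scan at the argmax of the two diagnosis logits, and
#' reports accuracy, AUC, confusion counts and throughput.
#'
#' @param model an [HGTModel].
#' @param data a [ScanDataset]; both classes must be present for AUC.
#' @param seed base seed of the evaluation-time slice draws.
#' @param zeroIndicators,zeroImages modality-isolation switches, see
#'   [hgtPredict()].
#' @param jsonOut optional path; the report is additionally written as
#'   JSON.
#' @return list with `acc`, `auc`, `counts`, `throughput` (images/s),
#'   `scores`, `labels`, `predicted`.
#' @export
evaluateModel <- function(model, data, seed = 1L, zeroIndicators = FALSE,
                          zeroImages = FALSE, jsonOut = NULL) {
  nScans <- length(data)
  if (nScans == 0L) stop("empty split")
  cfg <- modelConfig(model)
  scores <- numeric(nScans)
  pred <- integer(nScans)
  labels <- integer(nScans)
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(nScans)) {
    scan <- data[[i]]
    out <- hgtPredict(model, scan, seed = seed + i,
                      zeroIndicators = zeroIndicators,
                      zeroImages = zeroImages)
    scores[i] <- out$prob
    pred[i] <- as.integer(out$logits[2] > out$logits[1])
    labels[i] <- scanLabel(scan)
  }
  elapsed <- max(proc.time()[["elapsed"]] - t0, 1e-9)
  counts <- confusionCounts(pred, labels)
  report <- list(acc = accuracy(counts), auc = rocAuc(scores, labels),
                 counts = as.list(counts),
                 throughput = throughput(nScans * cfg$nSamples, elapsed, 1L),
                 scores = scores, labels = labels, predicted = pred)
  if (!is.null(jsonOut))
    jsonlite::write_json(report, jsonOut, auto_unbox = TRUE, digits = NA)
  report
}
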