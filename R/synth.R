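# Synthetic multimodal scan generator.
#
# Emulates the structure of a clinical CT + indicator dataset: per scan a
# variable number of grayscale slices (an ellipse phantom with smooth
# low-frequency texture and pixel noise), a contiguous window of
# lesion-bearing slices in positive scans (a Gaussian blob at a fixed
# in-plane location across the window, as a real lesion spans consecutive
# slices), and class-conditional indicator distributions (two serology-like
# channels shifted upward for positives, binary history flags with
# class-dependent rates).  With all effect sizes at zero the two classes
# are statistically identical (the null generator).

#' Specification of a synthetic dataset
#'
#' @param nTrain,nTest,nValid scans per split.
#' @param posFraction fraction of positive scans per split.
#' @param sliceRange integer range (min, max) of slices per scan.
#' @param imageSize slice edge length in pixels.
#' @param lesionIntensity peak added intensity of the planted lesion blob
#'   (0 disables the image signal).
#' @param lesionFraction fraction of the slice stack covered by the
#'   contiguous lesion window.
#' @param indicatorShift upward shift of the two serology-like channels
#'   for positive scans (0 disables).
#' @param flagEffect increase of the Bernoulli rate of the binary history
#'   flags for positive scans (0 disables).
#' @param noiseSd pixel noise standard deviation.
#' @param seed integer seed; a fixed seed reproduces the dataset exactly.
#' @return named list of class `synthSpec`.
#' @export
synthSpec <- function(nTrain = 40L, nTest = 20L, nValid = 0L,
                      posFraction = 0.5, sliceRange = c(150L, 400L),
                      imageSize = 224L, lesionIntensity = 0.35,
                      lesionFraction = 0.3, indicatorShift = 0.25,
                      flagEffect = 0.3, noiseSd = 0.08, seed = 1L) {
  stopifnot(sliceRange[1] >= 1L, sliceRange[2] >= sliceRange[1],
            imageSize >= 8L, posFraction > 0, posFraction < 1)
  structure(list(nTrain = as.integer(nTrain), nTest = as.integer(nTest),
                 nValid = as.integer(nValid), posFraction = posFraction,
                 sliceRange = as.integer(sliceRange),
                 imageSize = as.integer(imageSize),
                 lesionIntensity = lesionIntensity,
                 lesionFraction = lesionFraction,
                 indicatorShift = indicatorShift, flagEffect = flagEffect,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "synthSpec")
}

# base rates of the class-conditional indicator model
.IND_BASE <- list(serologyMean = 0.3, serologySd = 0.12,
                  ageMean = 0.6, ageSd = 0.15, flagRate = 0.2)

.drawIndicators <- function(label, spec) {
  b <- .IND_BASE
  shift <- if (label == 1L) spec$indicatorShift else 0
  sero <- stats::rnorm(2L, b$serologyMean + shift, b$serologySd)
  site <- stats::rbinom(1L, 1L, 0.5)
  sex <- stats::rbinom(1L, 1L, 0.5)
  age <- stats::rnorm(1L, b$ageMean, b$ageSd)
  rate <- b$flagRate + if (label == 1L) spec$flagEffect else 0
  flags <- stats::rbinom(9L, 1L, min(max(rate, 0), 1))
  pmin(pmax(c(sero, site, sex, age, flags), 0), 1)
}

.phantomGeom <- function(h) {
  ax <- seq(-1, 1, length.out = h)
  list(xm = matrix(ax, h, h), ym = matrix(ax, h, h, byrow = TRUE),
       h = h)
}

.lowFreqField <- function(h) {
  coarse <- matrix(stats::rnorm(64L), 8L, 8L)
  EBImage::imageData(EBImage::resize(coarse, w = h, h = h))
}

.generateScan <- function(id, label, spec, geom) {
  n <- spec$sliceRange[1] +
    sample.int(spec$sliceRange[2] - spec$sliceRange[1] + 1L, 1L) - 1L
  h <- spec$imageSize
  body <- (geom$xm / 0.85)^2 + (geom$ym / 0.7)^2 <= 1
  slices <- array(0, c(h, h, n))
  # lesion geometry is always drawn so that the RNG stream (and hence the
  # background and indicator draws) is identical across effect sizes; the
  # blob is only added for positive scans with a non-zero intensity
  theta <- stats::runif(1L, 0, 2 * pi)
  r <- stats::runif(1L, 0, 0.4)
  cx <- r * cos(theta) * 0.85
  cy <- r * sin(theta) * 0.7
  rad <- stats::runif(1L, 0.10, 0.18)
  len <- min(n, max(3L, as.integer(round(spec$lesionFraction * n))))
  s0 <- sample.int(n - len + 1L, 1L)
  lesion <- NULL
  win <- integer(0)
  if (label == 1L && spec$lesionIntensity > 0) {
    lesion <- spec$lesionIntensity *
      exp(-((geom$xm - cx)^2 + (geom$ym - cy)^2) / (2 * rad^2))
    win <- s0:(s0 + len - 1L)
  }
  for (k in seq_len(n)) {
    img <- 0.45 * body + 0.15 * body * .lowFreqField(h) +
      stats::rnorm(h * h, sd = spec$noiseSd)
    if (k %in% win) img <- img + lesion
    slices[, , k] <- pmin(pmax(img, 0), 1)
  }
  CTScan(id, slices, .drawIndicators(label, spec), label)
}

.splitLabels <- function(nScans, posFraction) {
  npos <- as.integer(round(nScans * posFraction))
  c(rep(1L, npos), rep(0L, nScans - npos))
}

#' Generate a synthetic multimodal scan dataset in memory
#'
#' @param spec a [synthSpec()].
#' @return named list of [ScanDataset] objects, one per non-empty split
#'   (`train`, `test`, `valid`).
#' @export
generateSyntheticScans <- function(spec) {
  stopifnot(inherits(spec, "synthSpec"))
  .withSeed(spec$seed, {
    geom <- .phantomGeom(spec$imageSize)
    out <- list()
    for (split in c("train", "test", "valid")) {
      nScans <- spec[[paste0("n",
                             toupper(substr(split, 1, 1)),
                             substr(split, 2, nchar(split)))]]
      if (nScans == 0L) next
      labels <- .splitLabels(nScans, spec$posFraction)
      scans <- lapply(seq_len(nScans), function(i)
        .generateScan(sprintf("%s_%03d", split, i), labels[i], spec, geom))
      out[[split]] <- ScanDataset(scans)
    }
    out
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes 8-bit grayscale PNG slices (`<root>/<split>/<scan_id>/
#' slice_NNNN.png`, 0-based zero-padded slice index) and a CSV manifest
#' (`manifest.csv`: split, scan_id, label, n_slices, ind1..ind14).
#'
#' @param spec a [synthSpec()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data frame.
#' @export
generateSyntheticDataset <- function(spec, dir) {
  splits <- generateSyntheticScans(spec)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop(sprintf("cannot create output directory '%s'", dir))
  rows <- list()
  for (split in names(splits)) {
    ds <- splits[[split]]
    for (i in seq_len(length(ds))) {
      scan <- ds[[i]]
      sdir <- file.path(dir, split, scanId(scan))
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      for (k in seq_len(nSlices(scan)))
        png::writePNG(scan@slices[, , k],
                      file.path(sdir, sprintf("slice_%04d.png", k - 1L)))
      rows[[length(rows) + 1L]] <- data.frame(
        split = split, scan_id = scanId(scan), label = scanLabel(scan),
        n_slices = nSlices(scan),
        stats::setNames(as.data.frame(t(indicators(scan))),
                        paste0("ind", 1:14)),
        stringsAsFactors = FALSE)
    }
  }
  man <- do.call(rbind, rows)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a scan dataset from disk
#'
#' Reads the manifest written by [generateSyntheticDataset()] (or any
#' dataset laid out the same way) and loads the PNG slices of each scan
#' in slice-index order, regardless of file-listing order.
#'
#' @param root dataset root directory containing `manifest.csv`.
#' @param split optional split name to filter on.
#' @return a [ScanDataset].
#' @export
readDataset <- function(root, split = NULL) {
  mf <- file.path(root, "manifest.csv")
  if (!file.exists(mf)) stop(sprintf("no manifest at '%s'", mf))
  man <- utils::read.csv(mf, stringsAsFactors = FALSE)
  indCols <- paste0("ind", 1:14)
  missingCols <- setdiff(c("split", "scan_id", "label", "n_slices", indCols),
                         names(man))
  if (length(missingCols))
    stop(sprintf("manifest '%s' lacks columns: %s", mf,
                 paste(missingCols, collapse = ", ")))
  if (!is.null(split)) man <- man[man$split == split, , drop = FALSE]
  if (nrow(man) == 0L) stop("no scans in the requested split")
  scans <- lapply(seq_len(nrow(man)), function(r) {
    row <- man[r, ]
    ind <- as.numeric(row[indCols])
    if (any(is.na(ind)) || any(ind < 0) || any(ind > 1))
      stop(sprintf("manifest row %d (scan '%s'): indicators invalid or out of [0, 1]",
                   r, row$scan_id))
    sdir <- file.path(root, row$split, row$scan_id)
    files <- list.files(sdir, pattern = "^slice_\\d+\\.png$")
    if (length(files) != row$n_slices)
      stop(sprintf("scan '%s': expected %d slices under '%s', found %d",
                   row$scan_id, row$n_slices, sdir, length(files)))
    kidx <- as.integer(sub("^slice_(\\d+)\\.png$", "\\1", files))
    files <- files[order(kidx)]
    sl <- lapply(files, function(f) {
      img <- png::readPNG(file.path(sdir, f))
      if (length(dim(img)) == 3L) img <- img[, , 1]
      img
    })
    h <- nrow(sl[[1]])
    CTScan(row$scan_id, array(unlist(sl), c(h, ncol(sl[[1]]), length(sl))),
           ind, row$label)
  })
  ScanDataset(scans)
}
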