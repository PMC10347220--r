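# Small image sizes and slice counts keep these tests fast; the indicator
# model does not depend on either.

tinySpec <- function(...) {
  synthSpec(nTrain = 2L, nTest = 2L, sliceRange = c(3L, 5L),
            imageSize = 16L, seed = 11L, ...)
}

test_that("a fixed seed reproduces the dataset exactly", {
  s <- tinySpec()
  d1 <- generateSyntheticScans(s)
  d2 <- generateSyntheticScans(s)
  expect_identical(manifest(d1$train), manifest(d2$train))
  expect_identical(d1$train[[1]]@slices, d2$train[[1]]@slices)
  # and byte-identical files on disk
  r1 <- file.path(tempdir(), "synth_a")
  r2 <- file.path(tempdir(), "synth_b")
  generateSyntheticDataset(s, r1)
  generateSyntheticDataset(s, r2)
  expect_identical(readBin(file.path(r1, "manifest.csv"), "raw", 1e6),
                   readBin(file.path(r2, "manifest.csv"), "raw", 1e6))
  unlink(c(r1, r2), recursive = TRUE)
})

test_that("scans respect the configured shape constraints", {
  d <- generateSyntheticScans(tinySpec())
  expect_named(d, c("train", "test"))
  for (i in 1:2) {
    scan <- d$train[[i]]
    expect_true(nSlices(scan) >= 3L && nSlices(scan) <= 5L)
    expect_identical(dim(scan@slices)[1:2], c(16L, 16L))
    expect_true(all(scan@slices >= 0 & scan@slices <= 1))
    expect_length(indicators(scan), 14L)
  }
})

test_that("class-conditional indicator effects match the configured sizes", {
  # 200 scans; image size and slice count kept minimal for speed
  s <- synthSpec(nTrain = 200L, nTest = 0L, nValid = 0L,
                 sliceRange = c(1L, 1L), imageSize = 8L,
                 lesionIntensity = 0, indicatorShift = 0.25,
                 flagEffect = 0.3, seed = 21L)
  d <- generateSyntheticScans(s)
  man <- manifest(d$train)
  pos <- man[man$label == 1L, ]
  neg <- man[man$label == 0L, ]
  # serology channels shifted by ~0.25 (clipping at 1 bites only slightly)
  for (ch in c("ind1", "ind2")) {
    dm <- mean(pos[[ch]]) - mean(neg[[ch]])
    expect_gt(dm, 0.25 - 0.06)
    expect_lt(dm, 0.25 + 0.06)
  }
  # binary flags at rate 0.2 vs 0.5
  flagDiff <- mean(as.matrix(pos[paste0("ind", 6:14)])) -
    mean(as.matrix(neg[paste0("ind", 6:14)]))
  expect_gt(flagDiff, 0.3 - 0.06)
  expect_lt(flagDiff, 0.3 + 0.06)
})

test_that("the null generator makes the classes indistinguishable", {
  s <- synthSpec(nTrain = 120L, nTest = 0L, sliceRange = c(1L, 1L),
                 imageSize = 8L, lesionIntensity = 0, indicatorShift = 0,
                 flagEffect = 0, seed = 31L)
  man <- manifest(generateSyntheticScans(s)$train)
  pos <- man[man$label == 1L, ]
  neg <- man[man$label == 0L, ]
  expect_lt(abs(mean(pos$ind1) - mean(neg$ind1)), 0.08)
  expect_lt(abs(mean(as.matrix(pos[paste0("ind", 6:14)])) -
                  mean(as.matrix(neg[paste0("ind", 6:14)]))), 0.08)
})

test_that("the lesion occupies a contiguous slice window in positives only", {
  # the generator consumes the same RNG stream for every effect size, so
  # the signal and zero-intensity datasets differ exactly by the lesion
  mk <- function(intensity)
    generateSyntheticScans(synthSpec(nTrain = 6L, nTest = 0L,
                                     sliceRange = c(10L, 12L),
                                     imageSize = 32L,
                                     lesionIntensity = intensity,
                                     seed = 41L))$train
  withL <- mk(0.35)
  without <- mk(0)
  sawWindow <- FALSE
  for (i in 1:6) {
    a <- withL[[i]]
    b <- without[[i]]
    expect_identical(indicators(a), indicators(b))
    dmax <- vapply(seq_len(nSlices(a)), function(k)
      max(abs(a@slices[, , k] - b@slices[, , k])), 0)
    hot <- which(dmax > 0.01)
    if (scanLabel(a) == 1L) {
      expect_gte(length(hot), 3L)                      # spans >= 3 slices
      expect_identical(hot, seq(min(hot), max(hot)))   # contiguous
      expect_lt(length(hot), nSlices(a))               # not the whole scan
      sawWindow <- TRUE
    } else {
      expect_identical(a@slices, b@slices)             # negatives untouched
    }
  }
  expect_true(sawWindow)
})

test_that("the on-disk round trip preserves the dataset", {
  root <- file.path(tempdir(), "synth_rt")
  man <- generateSyntheticDataset(tinySpec(), root)
  ds <- readDataset(root, split = "train")
  expect_length(ds, 2L)
  manTrain <- man[man$split == "train", ]
  got <- manifest(ds)
  expect_identical(got$scan_id, manTrain$scan_id)
  expect_identical(got$n_slices, manTrain$n_slices)
  expect_equal(as.numeric(got$ind1), manTrain$ind1, tolerance = 1e-12)
  # PNG slices are 8-bit: values equal up to quantization
  orig <- generateSyntheticScans(tinySpec())$train[[1]]
  expect_lt(max(abs(ds[[1]]@slices - orig@slices)), 1 / 255)
  unlink(root, recursive = TRUE)
})

test_that("the reader validates manifests and slice files", {
  root <- file.path(tempdir(), "synth_bad")
  generateSyntheticDataset(tinySpec(), root)
  man <- read.csv(file.path(root, "manifest.csv"))
  # out-of-range indicator -> row named in the error
  man2 <- man
  man2$ind14[2] <- 1.5
  write.csv(man2, file.path(root, "manifest.csv"), row.names = FALSE)
  expect_error(readDataset(root), "row 2")
  # missing indicator column
  write.csv(man[, setdiff(names(man), "ind14")],
            file.path(root, "manifest.csv"), row.names = FALSE)
  expect_error(readDataset(root), "ind14")
  # missing slice file -> scan and path named
  write.csv(man, file.path(root, "manifest.csv"), row.names = FALSE)
  sdir <- file.path(root, "train", man$scan_id[1])
  file.remove(file.path(sdir, "slice_0000.png"))
  expect_error(readDataset(root, "train"), man$scan_id[1])
  unlink(root, recursive = TRUE)
})

test_that("slices come back in index order regardless of listing order", {
  root <- file.path(tempdir(), "synth_ord")
  dir.create(file.path(root, "train", "s1"), recursive = TRUE)
  # files named without padding: lexicographic order would put 10 before 2
  img2 <- matrix(0.2, 8, 8)
  img10 <- matrix(0.8, 8, 8)
  png::writePNG(img2, file.path(root, "train", "s1", "slice_2.png"))
  png::writePNG(img10, file.path(root, "train", "s1", "slice_10.png"))
  man <- data.frame(split = "train", scan_id = "s1", label = 0L,
                    n_slices = 2L,
                    t(setNames(rep(0.5, 14), paste0("ind", 1:14))))
  write.csv(man, file.path(root, "manifest.csv"), row.names = FALSE)
  ds <- readDataset(root)
  expect_equal(mean(ds[[1]]@slices[, , 1]), 0.2, tolerance = 1e-2)
  expect_equal(mean(ds[[1]]@slices[, , 2]), 0.8, tolerance = 1e-2)
  unlink(root, recursive = TRUE)
})
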