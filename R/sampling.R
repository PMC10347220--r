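# Slice-stack sampling: reduce a variable-length CT slice stack (N slices,
# indices 0..N-1) to exactly nSamples slices.  The default strategy
# partitions the index range into nSamples contiguous groups and draws one
# slice uniformly at random within each group, so repeated draws across
# training epochs eventually touch every slice while each draw stays
# evenly spread along the scan axis.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Partition slice indices into contiguous groups
#'
#' Splits the index range `0..nImages-1` into `nSamples` contiguous,
#' non-overlapping groups whose sizes differ by at most one.  When
#' `nImages` is not divisible by `nSamples` the remainder goes to the
#' earliest groups, so larger groups come first.
#'
#' @param nImages number of slices in the scan (positive integer).
#' @param nSamples number of groups, i.e. the target sample size.
#' @return list of `nSamples` integer vectors of 0-based slice indices,
#'   in order, jointly covering `0..nImages-1`.
#' @examples
#' partitionGroups(10, 4)  # sizes 3,3,2,2
#' @export
partitionGroups <- function(nImages, nSamples) {
  nImages <- as.integer(nImages)
  nSamples <- as.integer(nSamples)
  if (nSamples < 1L) stop("nSamples must be >= 1")
  if (nImages < nSamples)
    stop(sprintf("cannot sample %d slices from a scan with only %d slices",
                 nSamples, nImages))
  base <- nImages %/% nSamples
  rem <- nImages %% nSamples
  sizes <- rep(base, nSamples) + c(rep(1L, rem), rep(0L, nSamples - rem))
  ends <- cumsum(sizes)
  starts <- c(0L, ends[-nSamples])
  lapply(seq_len(nSamples), function(i) seq.int(starts[i], ends[i] - 1L))
}

#' Draw one slice per contiguous group
#'
#' @param groups list of contiguous index groups from [partitionGroups()].
#' @param seed optional integer seed; the RNG state is restored afterwards.
#' @return sorted integer vector with exactly one index per group.
#' @export
drawSample <- function(groups, seed = NULL) {
  if (length(groups) == 0L) stop("empty group list")
  .withSeed(seed, {
    idx <- vapply(groups, function(g) {
      if (length(g) == 1L) g else g[sample.int(length(g), 1L)]
    }, 0L)
    sort(idx)
  })
}

.SAMPLING_STRATEGIES <- c("uniform_random_groups", "equally_spaced",
                          "equally_spaced_random", "random")

#' Sample a fixed number of slice indices from a scan
#'
#' Four strategies are available:
#' \describe{
#'   \item{`uniform_random_groups`}{contiguous groups, one uniform draw per
#'     group (the recommended default).}
#'   \item{`equally_spaced`}{deterministic indices `round(i*N/NS)`.}
#'   \item{`equally_spaced_random`}{one shared random offset within the
#'     first stride, then a fixed stride `floor(N/NS)`.}
#'   \item{`random`}{uniform without replacement, sorted.}
#' }
#'
#' @param nImages number of slices in the scan.
#' @param nSamples target number of sampled slices; must not exceed
#'   `nImages` (short stacks are rejected, not padded).
#' @param strategy one of the strategy names above.
#' @param seed optional integer seed (ignored by `equally_spaced`).
#' @return strictly increasing integer vector of `nSamples` 0-based
#'   indices in `[0, nImages)`.
#' @examples
#' sampleSlices(12, 4, "equally_spaced")        # 0 3 6 9
#' sampleSlices(300, 64, seed = 1)
#' @export
sampleSlices <- function(nImages,
                         nSamples,
                         strategy = "uniform_random_groups",
                         seed = NULL) {
  strategy <- match.arg(strategy, .SAMPLING_STRATEGIES)
  nImages <- as.integer(nImages)
  nSamples <- as.integer(nSamples)
  if (nImages < nSamples)
    stop(sprintf("cannot sample %d slices from a scan with only %d slices",
                 nSamples, nImages))
  out <- switch(strategy,
    uniform_random_groups =
      drawSample(partitionGroups(nImages, nSamples), seed = seed),
    equally_spaced = {
      idx <- as.integer(round((seq_len(nSamples) - 1) * nImages / nSamples))
      idx <- pmin(idx, nImages - 1L)
      if (anyDuplicated(idx)) stop("equally spaced indices collide")
      idx
    },
    equally_spaced_random = .withSeed(seed, {
      stride <- nImages %/% nSamples
      offset <- sample.int(stride, 1L) - 1L
      offset + stride * (seq_len(nSamples) - 1L)
    }),
    random = .withSeed(seed, {
      sort(sample.int(nImages, nSamples) - 1L)
    })
  )
  as.integer(out)
}
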