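# Parameter initialization.  All learnable state lives in one flat named
# list of base matrices; names are dotted paths ("s2.b1.attn.wq", "om.w2",
# ...).  Weight matrices use Glorot-style normal init, biases and layer-norm
# shifts start at zero, layer-norm gains at one.

.initW <- function(din, dout) {
  matrix(stats::rnorm(din * dout, sd = sqrt(2 / (din + dout))), din, dout)
}

.initLinear <- function(p, pre, din, dout) {
  p[[paste0(pre, "w")]] <- .initW(din, dout)
  p[[paste0(pre, "b")]] <- matrix(0, 1, dout)
  p
}

.initLN <- function(p, pre, d) {
  p[[paste0(pre, "g")]] <- matrix(1, 1, d)
  p[[paste0(pre, "b")]] <- matrix(0, 1, d)
  p
}

.initAttn <- function(p, pre, d) {
  for (nm in c("wq", "wk", "wv", "wo")) p[[paste0(pre, nm)]] <- .initW(d, d)
  for (nm in c("bq", "bk", "bv", "bo")) p[[paste0(pre, nm)]] <- matrix(0, 1, d)
  p
}

.initUsaBlock <- function(p, pre, d, mlpRatio = 2) {
  p <- .initLN(p, paste0(pre, "ln1."), d)
  for (psi in c("psi1.", "psi2.", "psi3."))
    p <- .initLinear(p, paste0(pre, psi), d, d)
  p <- .initAttn(p, paste0(pre, "attn."), d)
  p <- .initLN(p, paste0(pre, "ln2."), d)
  p <- .initLinear(p, paste0(pre, "mlp1."), d, mlpRatio * d)
  p <- .initLinear(p, paste0(pre, "mlp2."), mlpRatio * d, d)
  p
}

.initBackboneBlock <- function(p, pre, d, mlpRatio = 2) {
  p <- .initLN(p, paste0(pre, "ln1."), d)
  p <- .initAttn(p, paste0(pre, "attn."), d)
  p <- .initLN(p, paste0(pre, "ln2."), d)
  p <- .initLinear(p, paste0(pre, "mlp1."), d, mlpRatio * d)
  p <- .initLinear(p, paste0(pre, "mlp2."), mlpRatio * d, d)
  p
}

#' Model configuration
#'
#' Assembles the configuration list for [hgtModel()].  The full-size
#' default targets clinical-scale inputs (224x224 slices, 64 sampled
#' slices per scan); `toy = TRUE` selects a small configuration
#' (64x64 slices, 16 sampled slices, widths 32-256) sized so that the
#' whole pipeline trains in minutes on one CPU.
#'
#' @param toy logical; use the small CPU-scale configuration.
#' @param imageSize,patchSize slice resolution and square patch edge.
#' @param widths,depths,heads per-stage channel widths, block counts and
#'   attention head counts (4 image stages).
#' @param nSamples number of slices sampled per scan.
#' @param sampling slice sampling strategy, see [sampleSlices()].
#' @param k neighbour count for index-KNN graph sparsification.
#' @param nFusionStages number of graph coarsening stages.
#' @param mRule keep-fraction per coarsening stage.
#' @param gcnNormalize `"row"` (divide each adjacency row by its neighbour
#'   count) or `"none"` (raw weights).
#' @param omegaHidden hidden widths of the 3-layer edge-scoring MLP.
#' @param phiHidden hidden width of the 2-layer node-scoring MLP.
#' @param mlpRatio hidden-width multiplier of transformer MLPs.
#' @param selectLoss `"selected"` (sum the select loss over kept nodes
#'   only) or `"all"` (over every node).
#' @param selectReduce `"sum"` or `"mean"` over nodes within a stage.
#' @return named configuration list.
#' @export
hgtConfig <- function(toy = FALSE,
                      imageSize = if (toy) 64L else 224L,
                      patchSize = if (toy) 8L else 7L,
                      widths = if (toy) c(32L, 64L, 128L, 256L)
                               else c(64L, 128L, 256L, 512L),
                      depths = if (toy) c(1L, 1L, 1L, 1L)
                               else c(2L, 2L, 4L, 2L),
                      heads = if (toy) c(2L, 2L, 4L, 4L)
                              else c(2L, 4L, 8L, 16L),
                      nSamples = if (toy) 16L else 64L,
                      sampling = "uniform_random_groups",
                      k = 2L,
                      nFusionStages = 3L,
                      mRule = 0.5,
                      gcnNormalize = c("row", "none"),
                      omegaHidden = c(64L, 32L),
                      phiHidden = 64L,
                      mlpRatio = 2L,
                      selectLoss = c("selected", "all"),
                      selectReduce = c("sum", "mean")) {
  gcnNormalize <- match.arg(gcnNormalize)
  selectLoss <- match.arg(selectLoss)
  selectReduce <- match.arg(selectReduce)
  stopifnot(length(widths) == 4L, length(depths) == 4L, length(heads) == 4L,
            all(widths %% heads == 0L), imageSize %% patchSize == 0L)
  # three 2x2 patch merges halve the token grid three times
  grid <- imageSize %/% patchSize
  stopifnot(grid %% 8L == 0L)
  list(imageSize = as.integer(imageSize), patchSize = as.integer(patchSize),
       widths = as.integer(widths), depths = as.integer(depths),
       heads = as.integer(heads), nSamples = as.integer(nSamples),
       sampling = sampling, k = as.integer(k),
       nFusionStages = as.integer(nFusionStages), mRule = mRule,
       gcnNormalize = gcnNormalize,
       omegaHidden = as.integer(omegaHidden), phiHidden = as.integer(phiHidden),
       mlpRatio = as.integer(mlpRatio), selectLoss = selectLoss,
       selectReduce = selectReduce, nIndicators = .N_INDICATORS)
}

#' HGTModel: the multimodal fusion model
#'
#' Holds the flat named list of parameter matrices and the configuration.
#'
#' @slot params named list of numeric matrices.
#' @slot config configuration list from [hgtConfig()].
#' @export
setClass("HGTModel", representation(params = "list", config = "list"))

#' @rdname HGTModel-class
#' @param config configuration from [hgtConfig()].
#' @param seed integer seed for weight initialization.
#' @export
hgtModel <- function(config = hgtConfig(toy = TRUE), seed = 1L) {
  .withSeed(seed, {
    w <- config$widths
    p <- list()
    # indicator encoder (linear, width kept at 14) and lift to stage-1 width
    p <- .initLinear(p, "enc.", config$nIndicators, config$nIndicators)
    p <- .initLinear(p, "lift.", config$nIndicators, w[1])
    # patch embedding + learnable positional embedding
    grid <- config$imageSize %/% config$patchSize
    p <- .initLinear(p, "pe.", config$patchSize^2, w[1])
    p$pos <- matrix(stats::rnorm(grid^2 * w[1], sd = 0.02), grid^2, w[1])
    for (s in 1:4) {
      for (b in seq_len(config$depths[s]))
        p <- .initBackboneBlock(p, sprintf("s%d.b%d.", s, b), w[s],
                                config$mlpRatio)
      p <- .initUsaBlock(p, sprintf("us%d.", s), w[s], config$mlpRatio)
      if (s < 4) {
        p <- .initLinear(p, sprintf("pm%d.", s), 4L * w[s], w[s + 1])
        p <- .initLinear(p, sprintf("tp%d.", s), w[s], w[s + 1])
      }
    }
    d <- w[4]
    # edge scorer Omega (3 layers), node scorer Phi (2 layers), per-stage W
    oh <- config$omegaHidden
    p <- .initLinear(p, "om1.", 2L * d + 1L, oh[1])
    p <- .initLinear(p, "om2.", oh[1], oh[2])
    p <- .initLinear(p, "om3.", oh[2], 1L)
    p <- .initLinear(p, "ph1.", d, config$phiHidden)
    p <- .initLinear(p, "ph2.", config$phiHidden, 2L)
    for (l in seq_len(config$nFusionStages)) {
      p <- .initLN(p, sprintf("fu%d.lnin.", l), d)
      p <- .initLN(p, sprintf("fu%d.lng.", l), d)
      p[[sprintf("fu%d.w", l)]] <- .initW(d, d)
    }
    # diagnosis head on [f_out, final text feature]
    p <- .initLinear(p, "head.", 2L * d, 2L)
    new("HGTModel", params = p, config = config)
  })
}

#' @rdname HGTModel-class
#' @param object an `HGTModel`.
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))
#' @rdname HGTModel-class
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))
#' @rdname HGTModel-class
#' @export
setGeneric("nParams", function(object) standardGeneric("nParams"))

#' @rdname HGTModel-class
#' @export
setMethod("modelParams", "HGTModel", function(object) object@params)
#' @rdname HGTModel-class
#' @export
setMethod("modelConfig", "HGTModel", function(object) object@config)
#' @rdname HGTModel-class
#' @export
setMethod("nParams", "HGTModel", function(object)
  sum(vapply(object@params, length, 0L)))

setMethod("show", "HGTModel", function(object) {
  cfg <- object@config
  cat(sprintf(paste0("HGTModel: %d parameters\n  image %dx%d, patch %d, ",
                     "widths %s, depths %s\n  %d sampled slices, k=%d, ",
                     "%d fusion stages\n"),
              nParams(object), cfg$imageSize, cfg$imageSize, cfg$patchSize,
              paste(cfg$widths, collapse = "/"),
              paste(cfg$depths, collapse = "/"),
              cfg$nSamples, cfg$k, cfg$nFusionStages))
})
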