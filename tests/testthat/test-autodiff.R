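# Central finite-difference checks of the reverse-mode gradients.

fdCheck <- function(fn, params, n = 25, eps = 1e-5, tol = 1e-4) {
  sf <- asNamespace("scanfuse")
  sf$adTapeStart()
  leaves <- sf$adParams(params)
  root <- fn(function(nm) leaves[[nm]])
  sf$adBackward(root)
  grads <- sf$adGrads(leaves)
  sf$adTapeStop()
  valueOf <- function(p) {
    sf$adTapeStart()
    lv <- sf$adParams(p)
    v <- fn(function(nm) lv[[nm]])$val[1]
    sf$adTapeStop()
    v
  }
  for (pick in seq_len(n)) {
    nm <- sample(names(params), 1)
    i <- sample(length(params[[nm]]), 1)
    p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
    p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - eps
    fd <- (valueOf(p2) - valueOf(p3)) / (2 * eps)
    g <- grads[[nm]][i]
    expect_lt(abs(fd - g) / max(1, abs(fd), abs(g)), tol)
  }
  invisible(grads)
}

test_that("multi-head attention gradients match finite differences", {
  set.seed(1)
  sf <- asNamespace("scanfuse")
  d <- 4L
  params <- c(usaAttentionParams(d, seed = 2),
              list(xq = matrix(rnorm(d), 1, d),
                   xkv = matrix(rnorm(3 * d), 3, d)))
  fn <- function(pg) {
    y <- sf$adMHA(pg("xq"), pg("xkv"), pg("xkv"),
                  pg("wq"), pg("bq"), pg("wk"), pg("bk"),
                  pg("wv"), pg("bv"), pg("wo"), pg("bo"), 2L)
    sf$adCrossEntropy(sf$adRowSums(y), 0L)
  }
  fdCheck(fn, params, n = 20)
})

test_that("per-slice self-attention gradients match finite differences", {
  set.seed(2)
  sf <- asNamespace("scanfuse")
  d <- 4L
  params <- c(usaAttentionParams(d, seed = 5),
              list(x = matrix(rnorm(6 * d), 6, d)))  # 2 slices x 3 tokens
  fn <- function(pg) {
    y <- sf$adSliceAttn(pg("x"), 3L,
                        pg("wq"), pg("bq"), pg("wk"), pg("bk"),
                        pg("wv"), pg("bv"), pg("wo"), pg("bo"), 2L)
    sf$adCrossEntropy(sf$adMeanRows(y), 1L)
  }
  fdCheck(fn, params, n = 20)
})

test_that("layer norm, gelu and gather/cbind gradients match finite differences", {
  set.seed(3)
  sf <- asNamespace("scanfuse")
  params <- list(x = matrix(rnorm(12), 4, 3),
                 g = matrix(rnorm(3), 1, 3), b = matrix(rnorm(3), 1, 3),
                 w = matrix(rnorm(6 * 2), 6, 2), wb = matrix(0, 1, 2))
  fn <- function(pg) {
    xn <- sf$adLayerNorm(pg("x"), pg("g"), pg("b"))
    gx <- sf$adGelu(xn)
    z <- sf$adCbind(list(sf$adGather(gx, c(1L, 3L, 3L, 2L)),
                         sf$adGather(gx, c(2L, 4L, 1L, 1L))))
    sf$adCrossEntropy(sf$adLinear(z, pg("w"), pg("wb")), c(0L, 1L, 1L, 0L))
  }
  fdCheck(fn, params, n = 20)
})

test_that("pmax symmetrization and reshape gradients match finite differences", {
  set.seed(4)
  sf <- asNamespace("scanfuse")
  params <- list(s = matrix(rnorm(9), 9, 1))
  mask <- scanfuse:::.knnMask(0:2, 1L)
  fn <- function(pg) {
    S <- sf$adReshapeRM(pg("s"), 3L, 3L)
    am <- sf$adConstAdd(sf$adConstMul(S, mask * 1), -1e30 * !mask)
    asym <- sf$adPmax2(am, sf$adTranspose(am))
    a <- sf$adConstMul(asym, (mask | t(mask)) * 1)
    sf$adCrossEntropy(sf$adMM(a, sf$adConst(matrix(c(1, 2, -1, 0.5, 1, 0),
                                                   3, 2))),
                      c(0L, 1L, 0L))
  }
  fdCheck(fn, params, n = 9)
})

test_that("the full model loss gradient matches finite differences", {
  set.seed(7)
  sf <- asNamespace("scanfuse")
  cfg <- hgtConfig(toy = TRUE, imageSize = 16L, patchSize = 2L,
                   widths = c(4L, 8L, 8L, 8L), depths = c(1L, 1L, 1L, 1L),
                   heads = c(2L, 2L, 2L, 2L), nSamples = 6L,
                   omegaHidden = c(8L, 6L), phiHidden = 8L)
  m <- hgtModel(cfg, seed = 3)
  sl <- array(runif(16 * 16 * 6), c(16, 16, 6))
  ind <- runif(14)
  idx <- c(0L, 2L, 3L, 5L, 8L, 9L)
  fn <- function(pg) {
    sf$.scanLossNodes(pg, cfg, sl, ind, idx, 1L)$total
  }
  fdCheck(fn, modelParams(m), n = 30)
})

test_that("tape forward values equal the pure implementations", {
  set.seed(9)
  d <- 6L
  p <- usaAttentionParams(d, seed = 1)
  q <- matrix(rnorm(d), 1, d)
  kv <- matrix(rnorm(4 * d), 4, d)
  sf <- asNamespace("scanfuse")
  nd <- sf$adMHA(sf$adConst(q), sf$adConst(kv), sf$adConst(kv),
                 sf$adConst(p$wq), sf$adConst(p$bq), sf$adConst(p$wk),
                 sf$adConst(p$bk), sf$adConst(p$wv), sf$adConst(p$bv),
                 sf$adConst(p$wo), sf$adConst(p$bo), 2L)
  expect_equal(nd$val, usaAttention(q, kv, kv, p, 2L))
})
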