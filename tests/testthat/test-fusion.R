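test_that("pairwiseRelation concatenates features with their squared distance", {
  v <- c(0.2, -1, 3)
  expect_equal(pairwiseRelation(v, v), c(v, v, 0))
  expect_equal(pairwiseRelation(c(1, 0), c(0, 1)), c(1, 0, 0, 1, 2))
  expect_length(pairwiseRelation(rnorm(3), rnorm(3)), 7L)
  expect_error(pairwiseRelation(rnorm(3), rnorm(4)), "width")
})

test_that("denseAdjacency scores every ordered pair through the edge MLP", {
  set.seed(21)
  d <- 2L
  p <- omegaParams(d, hidden = c(5L, 4L), seed = 3)
  # identical node features: one value off-diagonal, one on the diagonal
  f <- matrix(rep(c(0.4, -0.2), each = 3), 3, d)
  S <- denseAdjacency(f, p)
  expect_equal(length(unique(round(S[upper.tri(S) | lower.tri(S)], 12))), 1L)
  expect_equal(length(unique(round(diag(S), 12))), 1L)
  # zero-weight final layer: S is constantly the bias
  p0 <- p
  p0$om3.w <- matrix(0, nrow(p0$om3.w), 1)
  p0$om3.b <- matrix(0.7, 1, 1)
  expect_true(all(denseAdjacency(matrix(rnorm(8), 4, d), p0) == 0.7))
  # loop oracle
  f <- matrix(rnorm(6), 3, d)
  expect_equal(denseAdjacency(f, p), oracleDenseAdjacency(f, p),
               tolerance = 1e-10)
  expect_error(denseAdjacency(matrix(rnorm(2), 1, 2), p), "2 nodes")
  expect_error(denseAdjacency(matrix(c(1, NA, 1, 1), 2, 2), p), "finite")
})

test_that("knnSparsify keeps index-nearest neighbours and symmetrizes", {
  set.seed(44)
  S <- matrix(rnorm(16), 4, 4)
  A <- as.matrix(knnSparsify(S, 0:3, k = 2))
  expect_true(all(A == t(A)))
  # hand-enumerated union support for indices 0..3, k = 2: every pair at
  # index distance <= 2 is connected, the (0,3) pair is not
  expect_true(all((A != 0) == (abs(outer(0:3, 0:3, `-`)) %in% 1:2)))
  # retained symmetric weight is the max of the two directed scores
  expect_equal(A[1, 2], max(S[1, 2], S[2, 1]))
  # directed neighbour sets before symmetrization: N(0)={1,2}, N(1)={0,2}
  m <- scanfuse:::.knnMask(0:3, 2L)
  expect_identical(which(m[1, ]), c(2L, 3L))
  expect_identical(which(m[2, ]), c(1L, 3L))
  expect_identical(which(m[3, ]), c(2L, 4L))
  expect_identical(which(m[4, ]), c(2L, 3L))
})

test_that("knnSparsify keeps an edge present in either direction", {
  # indices 0, 10, 11 with k = 1: N(0)={10}, N(10)={11}, N(11)={10};
  # the (0,10) edge exists only directed but must survive symmetrization
  S <- matrix(rnorm(9), 3, 3)
  A <- as.matrix(knnSparsify(S, c(0L, 10L, 11L), k = 1))
  expect_true(A[1, 2] != 0 && A[2, 1] != 0)
  expect_equal(A[1, 2], A[2, 1])
  expect_true(A[1, 3] == 0 && A[3, 1] == 0)
})

test_that("knnSparsify with k = n-1 has full off-diagonal support", {
  S <- matrix(rnorm(25), 5, 5)
  A <- as.matrix(knnSparsify(S, 0:4, k = 4))
  expect_true(all(A[upper.tri(A) | lower.tri(A)] != 0))
  expect_true(all(diag(A) == 0))
  expect_error(knnSparsify(S, 0:4, k = 5), "smaller than")
})

test_that("gcnBlock is the residual identity at W = 0 and matches the oracle", {
  set.seed(5)
  d <- 2L
  n <- 3L
  f <- matrix(rnorm(n * d), n, d)
  A <- knnSparsify(matrix(rnorm(n * n), n, n), 0:(n - 1), 1)
  pr <- list(lnin.g = matrix(rnorm(d), 1), lnin.b = matrix(rnorm(d), 1),
             lng.g = matrix(rnorm(d), 1), lng.b = matrix(rnorm(d), 1),
             w = matrix(rnorm(d * d), d, d))
  p0 <- pr
  p0$w <- matrix(0, d, d)
  expect_identical(gcnBlock(f, A, p0), f)
  # isolated nodes: output is the input plus one constant row
  outZ <- gcnBlock(f, matrix(0, n, n), pr)
  shift <- outZ - f
  expect_equal(shift[1, ], shift[2, ])
  expect_equal(shift[1, ], shift[3, ])
  for (norm in c("row", "none"))
    expect_equal(gcnBlock(f, A, pr, norm), oracleGcnBlock(f, A, pr, norm),
                 tolerance = 1e-6)
})

test_that("fsaSelect keeps the top-M max-score nodes in original order", {
  set.seed(8)
  d <- 4L
  p <- phiParams(d, hidden = 6L, seed = 2)
  f <- matrix(rnorm(5 * d), 5, d)
  all_ <- fsaSelect(f, p, M = 5L)
  expect_identical(all_$positions, 1:5)       # M = n keeps everything
  expect_identical(all_$features, f)
  sel <- fsaSelect(f, p, M = 2L)
  expect_identical(sel$positions, sort(sel$positions))
  expect_identical(sel$features, f[sel$positions, ])
  expect_identical(dim(sel$logits), c(5L, 2L))
  expect_error(fsaSelect(f, p, M = 6L), "exceeds")
})

test_that("fsaSelect agrees with brute-force subset enumeration", {
  set.seed(12)
  for (trial in 1:25) {
    n <- sample(2:8, 1)
    M <- sample(seq_len(n), 1)
    d <- 3L
    p <- phiParams(d, hidden = 5L)
    f <- matrix(rnorm(n * d), n, d)
    sel <- fsaSelect(f, p, M)
    scores <- apply(oraclePhi(f, p), 1, max)
    expect_equal(sel$scores, scores, tolerance = 1e-10)
    expect_identical(sel$positions, oracleTopM(scores, M))
  }
})

test_that("fsaSelect breaks score ties toward the smallest positions", {
  d <- 3L
  p <- phiParams(d, hidden = 5L, seed = 7)
  base <- rnorm(d)
  # all rows identical: every score ties, so the smallest positions win
  f <- rbind(base, base, base, base)
  sel <- fsaSelect(f, p, M = 2L)
  expect_identical(sel$positions, c(1L, 2L))
  expect_identical(fsaSelect(f, p, M = 3L)$positions, c(1L, 2L, 3L))
})

test_that("fsaSelect commutes with node permutations (up to tie-breaks)", {
  set.seed(3)
  d <- 4L
  p <- phiParams(d, seed = 5)
  f <- matrix(rnorm(6 * d), 6, d)
  sel <- fsaSelect(f, p, M = 3L)
  perm <- sample(6)
  selP <- fsaSelect(f[perm, ], p, M = 3L)
  expect_setequal(perm[selP$positions], sel$positions)
})

test_that("each fusion stage rebuilds its graph from the survivors only", {
  set.seed(61)
  m <- hgtModel(hgtConfig(toy = TRUE, imageSize = 16L, patchSize = 2L,
                          widths = c(4L, 8L, 8L, 8L), depths = rep(1L, 4),
                          heads = rep(2L, 4), nSamples = 8L,
                          omegaHidden = c(8L, 6L), phiHidden = 8L),
                seed = 4)
  p <- modelParams(m)
  d <- 8L
  f <- matrix(rnorm(8 * d), 8, d)
  out <- fusionNetForward(f, 0:7, p, k = 2L, nStages = 3L)
  # recompose stage 2 by hand from the stage-1 survivors: identical result
  s1 <- out$stages[[1]]
  surv <- nodeFeatures(s1$graph)[s1$positions, , drop = FALSE]
  idx <- s1$keptSliceIndices
  S2 <- denseAdjacency(surv, p)
  A2 <- knnSparsify(S2, idx, 2L)
  fl2 <- list(`lnin.g` = p[["fu2.lnin.g"]], `lnin.b` = p[["fu2.lnin.b"]],
              `lng.g` = p[["fu2.lng.g"]], `lng.b` = p[["fu2.lng.b"]],
              w = p[["fu2.w"]])
  expect_equal(nodeFeatures(out$stages[[2]]$graph),
               gcnBlock(surv, A2, fl2, "row"), tolerance = 1e-12)
  # consequently a dropped node has no downstream influence: the stage-2
  # result recomposed above never reads the dropped rows
  expect_identical(nrow(S2), length(s1$positions))
  expect_identical(out$nodeCounts, c(8L, 4L, 2L, 1L))
})
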