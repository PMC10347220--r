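# GCN feature-fusion head.  A learned dense affinity over per-slice
# features is sparsified to the k nearest neighbours in slice-index
# distance, symmetrized, passed through a residual GCN block, and
# coarsened by keeping the M nodes with the highest max-entry of a small
# scoring MLP (FSA).  Three stages halve the node count each time; the
# mean of the survivors is the fused scan feature.

.linF <- function(x, w, b) sweep(x %*% w, 2L, as.numeric(b), `+`)

.lnF <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd_ <- sqrt(rowMeans(xc * xc) + eps)
  sweep((xc / sd_) * rep(1, nrow(x)) %o% as.numeric(g), 2L,
        as.numeric(b), `+`)
}

#' Pairwise spatial relation of two feature vectors
#'
#' Concatenates the two vectors and their squared Euclidean distance into
#' the edge-scorer input of length `2*dim + 1`.
#'
#' @param fi,fj numeric vectors of equal length.
#' @return numeric vector `c(fi, fj, ||fi - fj||^2)`.
#' @examples
#' pairwiseRelation(c(1, 0), c(0, 1))  # 1 0 0 1 2
#' @export
pairwiseRelation <- function(fi, fj) {
  fi <- as.numeric(fi); fj <- as.numeric(fj)
  if (length(fi) != length(fj)) stop("feature widths disagree")
  c(fi, fj, sum((fi - fj)^2))
}

#' Initialize the edge-scoring MLP (Omega)
#'
#' Three linear layers with GeLU activations mapping the pairwise
#' relation vector to a scalar edge weight.
#'
#' @param dim node feature width.
#' @param hidden two hidden widths.
#' @param seed optional seed.
#' @return flat named parameter list (`om1.*`, `om2.*`, `om3.*`).
#' @export
omegaParams <- function(dim, hidden = c(64L, 32L), seed = NULL) {
  .withSeed(seed, {
    p <- .initLinear(list(), "om1.", 2L * dim + 1L, hidden[1])
    p <- .initLinear(p, "om2.", hidden[1], hidden[2])
    .initLinear(p, "om3.", hidden[2], 1L)
  })
}

.omegaF <- function(g, params) {
  h <- .gelu(.linF(g, params[["om1.w"]], params[["om1.b"]]))
  h <- .gelu(.linF(h, params[["om2.w"]], params[["om2.b"]]))
  .linF(h, params[["om3.w"]], params[["om3.b"]])
}

#' Dense learned affinity matrix
#'
#' Applies the edge scorer to every ordered pair of node features.
#'
#' @param features `n x d` node feature matrix (`n >= 2`).
#' @param params parameters from [omegaParams()].
#' @return dense `n x n` matrix `S` with `S[i, j]` the scalar score of the
#'   ordered pair `(i, j)`.
#' @export
denseAdjacency <- function(features, params) {
  n <- nrow(features)
  if (n < 2L) stop("need at least 2 nodes")
  if (any(!is.finite(features))) stop("non-finite node features")
  ii <- rep(seq_len(n), each = n)
  jj <- rep(seq_len(n), times = n)
  fi <- features[ii, , drop = FALSE]
  fj <- features[jj, , drop = FALSE]
  g <- cbind(fi, fj, rowSums((fi - fj)^2))
  matrix(.omegaF(g, params), n, n, byrow = TRUE)
}

# k index-nearest neighbours of each node; ties in index distance break
# toward the smaller slice index.  mask[i, j] = TRUE iff j in N(i).
.knnMask <- function(sliceIndices, k) {
  n <- length(sliceIndices)
  mask <- matrix(FALSE, n, n)
  if (k < 1L) return(mask)
  for (i in seq_len(n)) {
    d <- abs(sliceIndices - sliceIndices[i])
    ord <- order(d, sliceIndices)
    ord <- ord[ord != i]
    mask[i, ord[seq_len(k)]] <- TRUE
  }
  mask
}

#' Index-based KNN sparsification of a dense affinity matrix
#'
#' Each node keeps its `k` nearest neighbours in slice-index distance
#' (ties toward the smaller index); the retained directed weights are then
#' symmetrized by the elementwise maximum over the union of supports, so
#' an edge present in either direction survives with the larger score.
#' The diagonal is zero (no self-loops; the GCN residual plays that role).
#'
#' @param S dense `n x n` affinity matrix.
#' @param sliceIndices original slice index of each node.
#' @param k neighbour count, `1 <= k < n`.
#' @return sparse symmetric `Matrix` of class `dgCMatrix`/`dsCMatrix`.
#' @export
knnSparsify <- function(S, sliceIndices, k) {
  n <- nrow(S)
  if (k >= n) stop(sprintf("k = %d must be smaller than n = %d", k, n))
  if (k < 1L) stop("k must be >= 1")
  mask <- .knnMask(sliceIndices, k)
  am <- ifelse(mask, S, -Inf)
  asym <- pmax(am, t(am))
  a <- ifelse(mask | t(mask), asym, 0)
  Matrix::Matrix(a, sparse = TRUE)
}

#' Residual GCN block
#'
#' `F_mid = GeLU(LN_g(A_n %*% LN_in(F))) %*% W + F`, where `A_n` is the
#' adjacency, optionally row-normalized by each node's neighbour count.
#' Output width equals input width; with `W = 0` the block is the
#' identity.
#'
#' @param features `n x d` node features.
#' @param A `n x n` (sparse) adjacency.
#' @param params list with `lnin.g/b`, `lng.g/b` (layer norms) and `w`
#'   (the `d x d` weight).
#' @param normalize `"row"` or `"none"`.
#' @return `n x d` matrix.
#' @export
gcnBlock <- function(features, A, params, normalize = c("row", "none")) {
  normalize <- match.arg(normalize)
  A <- as.matrix(A)
  if (nrow(A) != nrow(features)) stop("adjacency/feature shape mismatch")
  if (normalize == "row") {
    deg <- pmax(rowSums(A != 0), 1)
    A <- A / deg
  }
  xl <- .lnF(features, params[["lnin.g"]], params[["lnin.b"]])
  ag <- A %*% xl
  gm <- .gelu(.lnF(ag, params[["lng.g"]], params[["lng.b"]]))
  gm %*% params[["w"]] + features
}

#' Initialize the node-scoring MLP (Phi)
#'
#' @param dim node feature width.
#' @param hidden hidden width.
#' @param seed optional seed.
#' @return flat named parameter list (`ph1.*`, `ph2.*`).
#' @export
phiParams <- function(dim, hidden = 64L, seed = NULL) {
  .withSeed(seed, {
    p <- .initLinear(list(), "ph1.", dim, hidden)
    .initLinear(p, "ph2.", hidden, 2L)
  })
}

.phiF <- function(x, params)
  .linF(.gelu(.linF(x, params[["ph1.w"]], params[["ph1.b"]])),
        params[["ph2.w"]], params[["ph2.b"]])

#' Max-score feature sampling (FSA)
#'
#' Scores every node by the maximum entry of the 2-way scoring MLP output
#' and keeps the `M` highest-scoring nodes in their original relative
#' order.  Ties break toward the smallest position.
#'
#' @param features `n x d` node features (`F_mid` of the stage).
#' @param params parameters from [phiParams()].
#' @param M number of nodes to keep, `1 <= M <= n`.
#' @return list with `features` (`M x d`), `positions` (kept row
#'   positions, increasing), `logits` (all `n` score rows, for the select
#'   loss) and `scores` (per-node max score).
#' @export
fsaSelect <- function(features, params, M) {
  n <- nrow(features)
  if (M > n) stop(sprintf("M = %d exceeds node count n = %d", M, n))
  if (M < 1L) stop("M must be >= 1")
  logits <- .phiF(features, params)
  scores <- apply(logits, 1L, max)
  sel <- sort(order(-scores)[seq_len(M)])
  list(features = features[sel, , drop = FALSE], positions = sel,
       logits = logits, scores = scores)
}

#' Full GCN feature-fusion forward pass
#'
#' Per stage: rebuild the dense affinity on the surviving nodes, sparsify
#' to index-KNN, apply the residual GCN block, and keep the top half of
#' the nodes by FSA score.  The fused scan feature is the mean of the
#' final survivors.
#'
#' @param features `n x d` per-slice feature matrix from the backbone
#'   (`n >= 2`).
#' @param sliceIndices original slice index per row.
#' @param params flat parameter list with `om*`, `ph*` and per-stage
#'   `fu<l>.*` entries (as produced inside [hgtModel()], or assembled
#'   from [omegaParams()], [phiParams()] and layer-norm/weight entries).
#' @param k KNN neighbour count (capped at `n - 1` per stage).
#' @param nStages number of coarsening stages.
#' @param mRule keep-fraction per stage (`M = max(1, floor(n * mRule))`).
#' @param gcnNormalize adjacency normalization, see [gcnBlock()].
#' @return list with `fOut` (length-`d` fused feature), `nodeCounts`
#'   (node count entering each stage, then the final count) and `stages`,
#'   a list with per-stage `graph` ([FeatureGraph]), `positions`,
#'   `selectLogits` and `keptSliceIndices`.
#' @export
fusionNetForward <- function(features, sliceIndices, params, k = 2L,
                             nStages = 3L, mRule = 0.5,
                             gcnNormalize = "row") {
  if (nrow(features) < 2L) stop("need at least 2 starting nodes")
  idx <- as.integer(sliceIndices)
  stopifnot(length(idx) == nrow(features))
  f <- features
  counts <- nrow(f)
  stages <- vector("list", nStages)
  for (l in seq_len(nStages)) {
    n <- nrow(f)
    if (n > 1L) {
      S <- denseAdjacency(f, params)
      A <- knnSparsify(S, idx, min(k, n - 1L))
    } else {
      A <- Matrix::Matrix(0, 1, 1, sparse = TRUE)
    }
    fl <- list(`lnin.g` = params[[sprintf("fu%d.lnin.g", l)]],
               `lnin.b` = params[[sprintf("fu%d.lnin.b", l)]],
               `lng.g` = params[[sprintf("fu%d.lng.g", l)]],
               `lng.b` = params[[sprintf("fu%d.lng.b", l)]],
               w = params[[sprintf("fu%d.w", l)]])
    fmid <- gcnBlock(f, A, fl, gcnNormalize)
    M <- max(1L, as.integer(floor(n * mRule)))
    sel <- fsaSelect(fmid, params, M)
    stages[[l]] <- list(graph = FeatureGraph(fmid, idx, A),
                        positions = sel$positions,
                        selectLogits = sel$logits,
                        keptSliceIndices = idx[sel$positions])
    f <- sel$features
    idx <- idx[sel$positions]
    counts <- c(counts, nrow(f))
  }
  list(fOut = colMeans(f), nodeCounts = counts, stages = stages)
}

# Tape version used during training; mirrors fusionNetForward().
.fusionNodes <- function(f1, sliceIndices, pg, cfg) {
  f <- f1
  idx <- as.integer(sliceIndices)
  counts <- nrow(f$val)
  phis <- vector("list", cfg$nFusionStages)
  sels <- vector("list", cfg$nFusionStages)
  for (l in seq_len(cfg$nFusionStages)) {
    n <- nrow(f$val)
    if (n > 1L) {
      ii <- rep(seq_len(n), each = n)
      jj <- rep(seq_len(n), times = n)
      fi <- adGather(f, ii)
      fj <- adGather(f, jj)
      df <- adSub(fi, fj)
      g <- adCbind(list(fi, fj, adRowSums(adEMul(df, df))))
      h <- adGelu(adLinear(g, pg("om1.w"), pg("om1.b")))
      h <- adGelu(adLinear(h, pg("om2.w"), pg("om2.b")))
      svec <- adLinear(h, pg("om3.w"), pg("om3.b"))
      s <- adReshapeRM(svec, n, n)
      mask <- .knnMask(idx, min(cfg$k, n - 1L))
      am <- adConstAdd(adConstMul(s, mask * 1), -1e30 * !mask)
      asym <- adPmax2(am, adTranspose(am))
      union <- mask | t(mask)
      a <- adConstMul(asym, union * 1)
      if (cfg$gcnNormalize == "row") {
        scale <- 1 / pmax(rowSums(union), 1)
        a <- adConstMul(a, matrix(scale, n, n))
      }
    } else {
      a <- adConst(matrix(0, 1, 1))
    }
    xl <- adLayerNorm(f, pg(sprintf("fu%d.lnin.g", l)),
                      pg(sprintf("fu%d.lnin.b", l)))
    ag <- adMM(a, xl)
    gm <- adGelu(adLayerNorm(ag, pg(sprintf("fu%d.lng.g", l)),
                             pg(sprintf("fu%d.lng.b", l))))
    fmid <- adAdd(adMM(gm, pg(sprintf("fu%d.w", l))), f)
    phi <- adLinear(adGelu(adLinear(fmid, pg("ph1.w"), pg("ph1.b"))),
                    pg("ph2.w"), pg("ph2.b"))
    scores <- apply(phi$val, 1L, max)
    M <- max(1L, as.integer(floor(n * cfg$mRule)))
    sel <- sort(order(-scores)[seq_len(M)])
    phis[[l]] <- phi
    sels[[l]] <- sel
    f <- adGather(fmid, sel)
    idx <- idx[sel]
    counts <- c(counts, nrow(f$val))
  }
  list(fOut = adMeanRows(f), phis = phis, sels = sels, counts = counts)
}
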