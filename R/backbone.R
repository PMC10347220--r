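# Hierarchical image backbone: patch embedding, four transformer stages
# with per-slice self-attention, 2x2 patch merging between stages
# (spatial tokens / 4, channel width doubled by a linear map), and a
# mean-pooled per-slice feature at the end of each stage that feeds the
# USA block of that stage.

# Linear pixel indices of each patch: `map[t, j]` is the index into an
# h x h slice matrix of the j-th pixel of token t.  Tokens are ordered
# row-major over the patch grid; pixels within a patch column-major.
.patchMap <- function(h, p) {
  g <- h %/% p
  pr <- rep(seq_len(p), times = p)
  pc <- rep(seq_len(p), each = p)
  tx <- rep(seq_len(g), times = g)
  ty <- rep(seq_len(g), each = g)
  R <- outer((ty - 1L) * p, pr, `+`)
  C <- outer((tx - 1L) * p, pc, `+`)
  (C - 1L) * h + R
}

# (h, w, N) slice stack -> (N * g^2) x p^2 token matrix, slice-major rows.
.patchifyStack <- function(slices, p) {
  d <- dim(slices)
  stopifnot(d[1] == d[2], d[1] %% p == 0L)
  map <- .patchMap(d[1], p)
  do.call(rbind, lapply(seq_len(d[3]), function(k) {
    sl <- slices[, , k]
    matrix(sl[map], nrow(map), ncol(map))
  }))
}

# Row indices of the four quadrants of every 2x2 token block, for all
# slices stacked slice-major; used to merge tokens between stages.
.mergeIdx <- function(g, nSlices) {
  gg <- g %/% 2L
  ux <- rep(seq_len(gg), times = gg)
  uy <- rep(seq_len(gg), each = gg)
  q1 <- (2L * uy - 2L) * g + (2L * ux - 1L)
  offs <- rep((seq_len(nSlices) - 1L) * g * g, each = gg * gg)
  lapply(list(q1, q1 + 1L, q1 + g, q1 + g + 1L),
         function(q) offs + rep(q, nSlices))
}

# One transformer block (pre-norm): x + SliceAttn(LN(x)); x + MLP(LN(x)).
.backboneBlockNodes <- function(x, tokensPerSlice, pg, pre, nHeads) {
  h1 <- adLayerNorm(x, pg(paste0(pre, "ln1.g")), pg(paste0(pre, "ln1.b")))
  a <- adSliceAttn(h1, tokensPerSlice,
                   pg(paste0(pre, "attn.wq")), pg(paste0(pre, "attn.bq")),
                   pg(paste0(pre, "attn.wk")), pg(paste0(pre, "attn.bk")),
                   pg(paste0(pre, "attn.wv")), pg(paste0(pre, "attn.bv")),
                   pg(paste0(pre, "attn.wo")), pg(paste0(pre, "attn.bo")),
                   nHeads)
  x <- adAdd(x, a)
  h2 <- adLayerNorm(x, pg(paste0(pre, "ln2.g")), pg(paste0(pre, "ln2.b")))
  m <- adLinear(h2, pg(paste0(pre, "mlp1.w")), pg(paste0(pre, "mlp1.b")))
  m <- adGelu(m)
  m <- adLinear(m, pg(paste0(pre, "mlp2.w")), pg(paste0(pre, "mlp2.b")))
  adAdd(x, m)
}

#' Initialize the parameters of one image stage
#'
#' @param dim stage width.
#' @param depth number of transformer blocks.
#' @param seed optional seed.
#' @param mlpRatio MLP hidden-width multiplier.
#' @return flat named parameter list (`b1.*`, `b2.*`, ...).
#' @export
imageStageParams <- function(dim, depth, seed = NULL, mlpRatio = 2L) {
  .withSeed(seed, {
    p <- list()
    for (b in seq_len(depth))
      p <- .initBackboneBlock(p, sprintf("b%d.", b), dim, mlpRatio)
    p
  })
}

#' Run one image stage over a stack of per-slice token sets
#'
#' Applies `depth` pre-norm transformer blocks in which self-attention is
#' restricted to tokens of the same slice, then mean-pools each slice's
#' tokens into one feature vector.  Slice order is preserved.
#'
#' @param tokens `(N * t) x d` token matrix, slices stacked in order,
#'   `t = tokensPerSlice` rows per slice.
#' @param tokensPerSlice tokens per slice.
#' @param params parameters from [imageStageParams()].
#' @param nHeads attention head count.
#' @param depth number of blocks present in `params`.
#' @return list with `tokens` (same shape as input) and `pooled`
#'   (`N x d`, one row per slice).
#' @export
imageStageForward <- function(tokens, tokensPerSlice, params, nHeads = 1L,
                              depth = 1L) {
  if (nrow(tokens) %% tokensPerSlice != 0L)
    stop("token row count is not a multiple of tokensPerSlice")
  pg <- .pgFromList(params)
  x <- adConst(tokens)
  for (b in seq_len(depth))
    x <- .backboneBlockNodes(x, tokensPerSlice, pg, sprintf("b%d.", b), nHeads)
  list(tokens = x$val,
       pooled = adPoolSlices(x, tokensPerSlice)$val)
}

# Full backbone + USA forward on tape.  `slices` is an (h, w, N) array of
# already-sampled slices, `ind` the indicator vector.  Returns nodes for
# the per-slice features entering fusion (F1), the final text feature,
# and the per-stage pooled image features (values only, for audits).
.backboneForwardNodes <- function(pg, cfg, slices, ind) {
  n <- dim(slices)[3]
  x <- adConst(.patchifyStack(slices, cfg$patchSize))
  x <- adLinear(x, pg("pe.w"), pg("pe.b"))
  x <- adAddTile(x, pg("pos"), n)
  ft <- adLinear(adConst(matrix(ind, nrow = 1)), pg("enc.w"), pg("enc.b"))
  ft <- adLinear(ft, pg("lift.w"), pg("lift.b"))
  g <- cfg$imageSize %/% cfg$patchSize
  stagePooled <- vector("list", 4L)
  pooled <- NULL
  for (s in 1:4) {
    tt <- g * g
    for (b in seq_len(cfg$depths[s]))
      x <- .backboneBlockNodes(x, tt, pg, sprintf("s%d.b%d.", s, b),
                               cfg$heads[s])
    pooled <- adPoolSlices(x, tt)
    stagePooled[[s]] <- pooled$val
    ft <- .usaBlockNodes(ft, pooled, pg, sprintf("us%d.", s), cfg$heads[s])
    if (s < 4L) {
      mi <- .mergeIdx(g, n)
      x <- adLinear(adCbind(lapply(mi, function(ii) adGather(x, ii))),
                    pg(sprintf("pm%d.w", s)), pg(sprintf("pm%d.b", s)))
      ft <- adLinear(ft, pg(sprintf("tp%d.w", s)), pg(sprintf("tp%d.b", s)))
      g <- g %/% 2L
    }
  }
  list(F1 = pooled, ft = ft, stagePooled = stagePooled)
}
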