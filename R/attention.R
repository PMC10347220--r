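# Unidirectional Selective Attention (USA).
#
# A single query built from the indicator ("text") feature attends over
# the text feature concatenated with all per-slice image features; only
# the text feature is updated, so information flows one way, from the
# image stream into the indicator stream, never back.

.pgFromList <- function(params) {
  leaves <- adParams(params)
  function(nm) {
    nd <- leaves[[nm]]
    if (is.null(nd)) stop(sprintf("missing parameter '%s'", nm))
    nd
  }
}

.asRow <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1)
}

#' Encode the clinical indicator vector
#'
#' Affine map of the 14-element indicator vector (the linear "text"
#' encoder producing the initial text feature).
#'
#' @param t numeric vector of length 14, entries in `[0, 1]`.
#' @param weights `14 x d` weight matrix.
#' @param bias length-`d` bias (or `1 x d` matrix).
#' @return `1 x d` matrix, the text feature.
#' @examples
#' encodeIndicators(rep(0.5, 14), diag(14), rep(0, 14))
#' @export
encodeIndicators <- function(t, weights, bias) {
  if (length(t) != .N_INDICATORS)
    stop(sprintf("indicator vector must have length %d, got %d",
                 .N_INDICATORS, length(t)))
  if (nrow(weights) != .N_INDICATORS)
    stop("weight matrix must have 14 rows")
  matrix(t, nrow = 1) %*% weights + matrix(as.numeric(bias), nrow = 1)
}

#' Build the USA query, key and value inputs
#'
#' The query comes from the text feature alone; keys and values come from
#' the concatenation of the text feature with all image features, giving
#' `N + 1` key/value rows.  No query is ever built from image features.
#'
#' @param ft `1 x d` text feature.
#' @param fi `N x d` image feature matrix (`N = 0` allowed).
#' @param params named list with `psi1.w/psi1.b` (query), `psi2.w/psi2.b`
#'   (key) and `psi3.w/psi3.b` (value) projection matrices.
#' @return list with `Q` (`1 x d`), `K` and `V` (`(N+1) x d`).
#' @export
usaQkv <- function(ft, fi, params) {
  ft <- .asRow(ft)
  if (is.null(fi)) fi <- matrix(0, 0, ncol(ft))
  if (ncol(fi) != ncol(ft) && nrow(fi) > 0)
    stop("text and image feature widths disagree")
  z <- rbind(ft, fi)
  lin <- function(x, pre)
    sweep(x %*% params[[paste0(pre, ".w")]], 2L,
          as.numeric(params[[paste0(pre, ".b")]]), `+`)
  list(Q = lin(ft, "psi1"), K = lin(z, "psi2"), V = lin(z, "psi3"))
}

#' Initialize multi-head attention parameters
#'
#' @param dim feature width (divisible by the head count).
#' @param seed optional seed.
#' @param identity if `TRUE`, all projections are identity maps with zero
#'   bias (useful for hand-checkable examples).
#' @return named list `wq,bq,wk,bk,wv,bv,wo,bo`.
#' @export
usaAttentionParams <- function(dim, seed = NULL, identity = FALSE) {
  .withSeed(seed, {
    p <- .initAttn(list(), "", dim)
    if (identity) for (nm in c("wq", "wk", "wv", "wo")) p[[nm]] <- diag(dim)
    p
  })
}

#' Multi-head unidirectional selective attention
#'
#' Scaled dot-product attention with a scale of `1/sqrt(head_width)` and a
#' softmax over the `N + 1` keys, computed per head on the column blocks
#' of the per-head projections, then concatenated and mapped by the output
#' projection.
#'
#' @param q query matrix (usually `1 x d`).
#' @param k,v key and value matrices (`(N+1) x d`).
#' @param params per-head projection parameters, see
#'   [usaAttentionParams()].
#' @param nHeads number of heads; `d` must be divisible by `nHeads`.
#' @return updated text feature, same shape as `q`.
#' @export
usaAttention <- function(q, k, v, params, nHeads = 1L) {
  q <- .asRow(q); k <- .asRow(k); v <- .asRow(v)
  if (any(!is.finite(q)) || any(!is.finite(k)) || any(!is.finite(v)))
    stop("non-finite attention inputs")
  if (ncol(q) %% nHeads != 0L)
    stop("width must be divisible by the head count")
  pg <- .pgFromList(params)
  adMHA(adConst(q), adConst(k), adConst(v),
        pg("wq"), pg("bq"), pg("wk"), pg("bk"),
        pg("wv"), pg("bv"), pg("wo"), pg("bo"), nHeads)$val
}

# Tape-level USA block; `pg` resolves parameter leaf nodes by name and
# `pre` is the parameter name prefix (e.g. "us2.").
.usaBlockNodes <- function(ft, fi, pg, pre, nHeads) {
  z <- if (!is.null(fi) && nrow(fi$val) > 0) adRbind2(ft, fi) else ft
  zn <- adLayerNorm(z, pg(paste0(pre, "ln1.g")), pg(paste0(pre, "ln1.b")))
  qsrc <- adGather(zn, 1L)
  q0 <- adLinear(qsrc, pg(paste0(pre, "psi1.w")), pg(paste0(pre, "psi1.b")))
  k0 <- adLinear(zn, pg(paste0(pre, "psi2.w")), pg(paste0(pre, "psi2.b")))
  v0 <- adLinear(zn, pg(paste0(pre, "psi3.w")), pg(paste0(pre, "psi3.b")))
  att <- adMHA(q0, k0, v0,
               pg(paste0(pre, "attn.wq")), pg(paste0(pre, "attn.bq")),
               pg(paste0(pre, "attn.wk")), pg(paste0(pre, "attn.bk")),
               pg(paste0(pre, "attn.wv")), pg(paste0(pre, "attn.bv")),
               pg(paste0(pre, "attn.wo")), pg(paste0(pre, "attn.bo")), nHeads)
  ft1 <- adAdd(ft, att)
  h <- adLayerNorm(ft1, pg(paste0(pre, "ln2.g")), pg(paste0(pre, "ln2.b")))
  m <- adLinear(h, pg(paste0(pre, "mlp1.w")), pg(paste0(pre, "mlp1.b")))
  m <- adGelu(m)
  m <- adLinear(m, pg(paste0(pre, "mlp2.w")), pg(paste0(pre, "mlp2.b")))
  adAdd(ft1, m)
}

#' Initialize the parameters of one USA block
#'
#' @param dim feature width.
#' @param seed optional seed.
#' @param mlpRatio hidden-width multiplier of the block MLP.
#' @return flat named parameter list (`ln1.*`, `psi1..3.*`, `attn.*`,
#'   `ln2.*`, `mlp1.*`, `mlp2.*`).
#' @export
usaBlockParams <- function(dim, seed = NULL, mlpRatio = 2L) {
  .withSeed(seed, .initUsaBlock(list(), "", dim, mlpRatio))
}

#' One USA block (pre-norm residual layout)
#'
#' `ft + USA(LN([ft; fi]))` followed by `ft + MLP(LN(ft))`; the image
#' features are not modified (they are not even returned).
#'
#' @param ft `1 x d` text feature.
#' @param fi `N x d` image features (`N = 0` allowed).
#' @param params parameters from [usaBlockParams()].
#' @param nHeads attention head count.
#' @return updated `1 x d` text feature.
#' @export
usaBlock <- function(ft, fi, params, nHeads = 1L) {
  ft <- .asRow(ft)
  if (is.null(fi)) fi <- matrix(0, 0, ncol(ft))
  if (nrow(fi) > 0 && ncol(fi) != ncol(ft))
    stop("text and image feature widths disagree")
  pg <- .pgFromList(params)
  .usaBlockNodes(adConst(ft), adConst(fi), pg, "", nHeads)$val
}
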