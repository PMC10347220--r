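# Reverse-mode automatic differentiation over dense matrices.
#
# Every tracked value is a node: an environment holding the forward value
# (`val`, always a base matrix), the accumulated gradient (`grad`), the
# parent nodes and a backward closure that maps the node's output gradient
# to one gradient per parent.  Nodes are appended to a single active tape
# in execution order; adBackward() walks the tape in reverse.
#
# The engine is internal.  It supports exactly the operations the model
# needs; gradients are checked against central finite differences in the
# test suite.

.ad <- new.env(parent = emptyenv())
.ad$nodes <- NULL
.ad$n <- 0L

adTapeStart <- function() {
  .ad$nodes <- vector("list", 512L)
  .ad$n <- 0L
  invisible(NULL)
}

adTapeStop <- function() {
  .ad$nodes <- NULL
  .ad$n <- 0L
  invisible(NULL)
}

# req = TRUE for nodes that can receive gradients (params and anything
# computed from them); constants stay off the tape and are never updated.
adNode <- function(val, parents = list(), backward = NULL,
                   pname = NA_character_, req = TRUE) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$pname <- pname
  nd$req <- req
  if (req && !is.null(.ad$nodes)) {
    n <- .ad$n + 1L
    if (n > length(.ad$nodes))
      .ad$nodes <- c(.ad$nodes, vector("list", length(.ad$nodes)))
    .ad$nodes[[n]] <- nd
    .ad$n <- n
    nd$id <- n
  } else {
    nd$id <- 0L
  }
  nd
}

adConst <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  adNode(x, req = FALSE)
}

adLeaf <- function(x, pname) {
  if (!is.matrix(x)) x <- as.matrix(x)
  adNode(x, pname = pname)
}

# Wrap a flat named list of parameter matrices as leaf nodes.
adParams <- function(params) {
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) out[[nm]] <- adLeaf(params[[nm]], nm)
  out
}

# Collect gradients back into a named list aligned with `params`
# (zero matrices where a parameter was unused).
adGrads <- function(leaves) {
  out <- vector("list", length(leaves))
  names(out) <- names(leaves)
  for (nm in names(leaves)) {
    g <- leaves[[nm]]$grad
    if (is.null(g)) g <- array(0, dim(leaves[[nm]]$val))
    out[[nm]] <- g
  }
  out
}

.adAccum <- function(p, g) {
  if (!isTRUE(p$req) || is.null(g)) return(invisible(NULL))
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

adBackward <- function(root) {
  stopifnot(root$id > 0L)
  root$grad <- matrix(1, nrow(root$val), ncol(root$val))
  for (i in seq.int(root$id, 1L)) {
    nd <- .ad$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd)
    for (j in seq_along(nd$parents)) .adAccum(nd$parents[[j]], gs[[j]])
  }
  invisible(NULL)
}

## ---- elementary ops ------------------------------------------------------

adMM <- function(a, b) {
  adNode(a$val %*% b$val, list(a, b), function(nd) {
    g <- nd$grad
    list(tcrossprod(g, nd$parents[[2]]$val), crossprod(nd$parents[[1]]$val, g))
  }, req = a$req || b$req)
}

adAdd <- function(a, b) {
  adNode(a$val + b$val, list(a, b),
         function(nd) list(nd$grad, nd$grad), req = a$req || b$req)
}

adSub <- function(a, b) {
  adNode(a$val - b$val, list(a, b),
         function(nd) list(nd$grad, -nd$grad), req = a$req || b$req)
}

adEMul <- function(a, b) {
  adNode(a$val * b$val, list(a, b), function(nd) {
    list(nd$grad * nd$parents[[2]]$val, nd$grad * nd$parents[[1]]$val)
  }, req = a$req || b$req)
}

adScale <- function(a, s) {
  adNode(a$val * s, list(a), function(nd) list(nd$grad * s), req = a$req)
}

# Elementwise product with a constant matrix (masks, degree scalings).
adConstMul <- function(a, m) {
  adNode(a$val * m, list(a), local({
    mm <- m
    function(nd) list(nd$grad * mm)
  }), req = a$req)
}

adConstAdd <- function(a, m) {
  adNode(a$val + m, list(a), function(nd) list(nd$grad), req = a$req)
}

adTranspose <- function(a) {
  adNode(t(a$val), list(a), function(nd) list(t(nd$grad)), req = a$req)
}

adPmax2 <- function(a, b) {
  adNode(pmax(a$val, b$val), list(a, b), function(nd) {
    take_a <- nd$parents[[1]]$val >= nd$parents[[2]]$val
    list(nd$grad * take_a, nd$grad * !take_a)
  }, req = a$req || b$req)
}

adRowSums <- function(a) {
  adNode(matrix(rowSums(a$val), ncol = 1), list(a), function(nd) {
    list(matrix(nd$grad, nrow(nd$parents[[1]]$val),
                ncol(nd$parents[[1]]$val)))
  }, req = a$req)
}

adMeanRows <- function(a) {
  n <- nrow(a$val)
  adNode(matrix(colMeans(a$val), nrow = 1), list(a), local({
    nn <- n
    function(nd) {
      list(matrix(rep(nd$grad / nn, each = nn), nrow = nn))
    }
  }), req = a$req)
}

adRbind2 <- function(a, b) {
  na <- nrow(a$val)
  adNode(rbind(a$val, b$val), list(a, b), local({
    k <- na
    function(nd) {
      g <- nd$grad
      list(g[seq_len(k), , drop = FALSE], g[-seq_len(k), , drop = FALSE])
    }
  }), req = a$req || b$req)
}

adCbind <- function(lst) {
  widths <- vapply(lst, function(x) ncol(x$val), 0L)
  adNode(do.call(cbind, lapply(lst, `[[`, "val")), lst, local({
    w <- widths
    function(nd) {
      ends <- cumsum(w)
      starts <- c(1L, head(ends, -1L) + 1L)
      lapply(seq_along(w), function(j)
        nd$grad[, starts[j]:ends[j], drop = FALSE])
    }
  }), req = any(vapply(lst, `[[`, TRUE, "req")))
}

adGather <- function(a, idx) {
  adNode(a$val[idx, , drop = FALSE], list(a), local({
    ii <- idx
    function(nd) {
      g <- array(0, dim(nd$parents[[1]]$val))
      rs <- rowsum(nd$grad, ii)
      g[as.integer(rownames(rs)), ] <- rs
      list(g)
    }
  }), req = a$req)
}

# Row-major reshape of an (n*m) x 1 column into an n x m matrix,
# i.e. out[i, j] = a[(i-1)*m + j].
adReshapeRM <- function(a, n, m) {
  adNode(matrix(a$val, n, m, byrow = TRUE), list(a), local({
    function(nd) list(matrix(c(t(nd$grad)), ncol = 1))
  }), req = a$req)
}

## ---- neural-network ops --------------------------------------------------

.gelu <- function(x) x * stats::pnorm(x)
.geluGrad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

adGelu <- function(a) {
  adNode(.gelu(a$val), list(a), function(nd) {
    list(nd$grad * .geluGrad(nd$parents[[1]]$val))
  }, req = a$req)
}

# x %*% W + bias (bias a 1 x d matrix broadcast over rows)
adLinear <- function(x, w, b) {
  y <- x$val %*% w$val
  y <- sweep(y, 2L, as.numeric(b$val), `+`)
  adNode(y, list(x, w, b), function(nd) {
    g <- nd$grad
    list(tcrossprod(g, nd$parents[[2]]$val),
         crossprod(nd$parents[[1]]$val, g),
         matrix(colSums(g), nrow = 1))
  }, req = x$req || w$req || b$req)
}

# Row-wise layer normalization with learnable affine (gamma, beta: 1 x d).
adLayerNorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$val
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  sd_ <- sqrt(va + eps)
  xhat <- xc / sd_
  y <- sweep(xhat * rep(1, nrow(x)) %o% as.numeric(gamma$val), 2L,
             as.numeric(beta$val), `+`)
  nd <- adNode(y, list(a, gamma, beta), NULL,
               req = a$req || gamma$req || beta$req)
  nd$xhat <- xhat
  nd$sd_ <- sd_
  nd$backward <- function(nd) {
    g <- nd$grad
    gm <- as.numeric(nd$parents[[2]]$val)
    xhat <- nd$xhat
    dgamma <- matrix(colSums(g * xhat), nrow = 1)
    dbeta <- matrix(colSums(g), nrow = 1)
    dxhat <- sweep(g, 2L, gm, `*`)
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / nd$sd_
    list(dx, dgamma, dbeta)
  }
  nd
}

adSoftmaxRows <- function(a) {
  x <- a$val
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  y <- e / rowSums(e)
  nd <- adNode(y, list(a), NULL, req = a$req)
  nd$backward <- function(nd) {
    y <- nd$val
    g <- nd$grad
    list(y * (g - rowSums(g * y)))
  }
  nd
}

# Numerically stable softmax cross-entropy with integer class labels
# (0-based), summed over rows.  Returns a 1 x 1 node.
adCrossEntropy <- function(logits, y) {
  z <- logits$val
  zmax <- apply(z, 1L, max)
  lse <- zmax + log(rowSums(exp(z - zmax)))
  picked <- z[cbind(seq_len(nrow(z)), y + 1L)]
  loss <- sum(lse - picked)
  nd <- adNode(matrix(loss, 1, 1), list(logits), NULL, req = logits$req)
  nd$y <- y
  nd$backward <- function(nd) {
    z <- nd$parents[[1]]$val
    zmax <- apply(z, 1L, max)
    e <- exp(z - zmax)
    p <- e / rowSums(e)
    p[cbind(seq_len(nrow(z)), nd$y + 1L)] <-
      p[cbind(seq_len(nrow(z)), nd$y + 1L)] - 1
    list(as.numeric(nd$grad) * p)
  }
  nd
}

# Multi-head scaled-dot-product attention with separate query/key/value
# source matrices.  Per-head projections are the column blocks of the
# d x d matrices wq/wk/wv; wo maps the concatenated heads back to width d.
# One fused tape node keeps the tape short.
adMHA <- function(xq, xk, xv, wq, bq, wk, bk, wv, bv, wo, bo, n_heads) {
  d <- ncol(wq$val)
  stopifnot(d %% n_heads == 0L)
  dh <- d %/% n_heads
  q <- sweep(xq$val %*% wq$val, 2L, as.numeric(bq$val), `+`)
  k <- sweep(xk$val %*% wk$val, 2L, as.numeric(bk$val), `+`)
  v <- sweep(xv$val %*% wv$val, 2L, as.numeric(bv$val), `+`)
  o <- matrix(0, nrow(q), d)
  plist <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    ci <- ((h - 1L) * dh + 1L):(h * dh)
    s <- tcrossprod(q[, ci, drop = FALSE], k[, ci, drop = FALSE]) / sqrt(dh)
    s <- s - apply(s, 1L, max)
    e <- exp(s)
    p <- e / rowSums(e)
    plist[[h]] <- p
    o[, ci] <- p %*% v[, ci, drop = FALSE]
  }
  y <- sweep(o %*% wo$val, 2L, as.numeric(bo$val), `+`)
  nd <- adNode(y, list(xq, xk, xv, wq, bq, wk, bk, wv, bv, wo, bo), NULL,
               req = TRUE)
  nd$q <- q; nd$k <- k; nd$v <- v; nd$o <- o; nd$plist <- plist
  nd$n_heads <- n_heads
  nd$backward <- function(nd) {
    g <- nd$grad
    d <- ncol(nd$q)
    dh <- d %/% nd$n_heads
    wo_ <- nd$parents[[10]]$val
    dwo <- crossprod(nd$o, g)
    dbo <- matrix(colSums(g), nrow = 1)
    do_ <- tcrossprod(g, wo_)
    dq <- matrix(0, nrow(nd$q), d)
    dk <- matrix(0, nrow(nd$k), d)
    dv <- matrix(0, nrow(nd$v), d)
    for (h in seq_len(nd$n_heads)) {
      ci <- ((h - 1L) * dh + 1L):(h * dh)
      p <- nd$plist[[h]]
      dp <- tcrossprod(do_[, ci, drop = FALSE], nd$v[, ci, drop = FALSE])
      dv[, ci] <- crossprod(p, do_[, ci, drop = FALSE])
      ds <- p * (dp - rowSums(dp * p)) / sqrt(dh)
      dq[, ci] <- ds %*% nd$k[, ci, drop = FALSE]
      dk[, ci] <- crossprod(ds, nd$q[, ci, drop = FALSE])
    }
    xq_ <- nd$parents[[1]]$val
    xk_ <- nd$parents[[2]]$val
    xv_ <- nd$parents[[3]]$val
    wq_ <- nd$parents[[4]]$val
    wk_ <- nd$parents[[6]]$val
    wv_ <- nd$parents[[8]]$val
    list(tcrossprod(dq, wq_),                    # xq
         tcrossprod(dk, wk_),                    # xk
         tcrossprod(dv, wv_),                    # xv
         crossprod(xq_, dq), matrix(colSums(dq), nrow = 1),
         crossprod(xk_, dk), matrix(colSums(dk), nrow = 1),
         crossprod(xv_, dv), matrix(colSums(dv), nrow = 1),
         dwo, dbo)
  }
  nd
}

# Self-attention applied independently to consecutive blocks of
# `tokens_per_slice` rows (one block per slice).  A single tape node that
# loops over slices internally, forward and backward.
adSliceAttn <- function(x, tokens_per_slice, wq, bq, wk, bk, wv, bv, wo, bo,
                        n_heads) {
  tt <- tokens_per_slice
  n_rows <- nrow(x$val)
  stopifnot(n_rows %% tt == 0L)
  n_slices <- n_rows %/% tt
  d <- ncol(wq$val)
  dh <- d %/% n_heads
  q <- sweep(x$val %*% wq$val, 2L, as.numeric(bq$val), `+`)
  k <- sweep(x$val %*% wk$val, 2L, as.numeric(bk$val), `+`)
  v <- sweep(x$val %*% wv$val, 2L, as.numeric(bv$val), `+`)
  o <- matrix(0, n_rows, d)
  plist <- vector("list", n_slices * n_heads)
  for (s in seq_len(n_slices)) {
    rr <- ((s - 1L) * tt + 1L):(s * tt)
    for (h in seq_len(n_heads)) {
      ci <- ((h - 1L) * dh + 1L):(h * dh)
      sc <- tcrossprod(q[rr, ci, drop = FALSE], k[rr, ci, drop = FALSE]) /
        sqrt(dh)
      sc <- sc - apply(sc, 1L, max)
      e <- exp(sc)
      p <- e / rowSums(e)
      plist[[(s - 1L) * n_heads + h]] <- p
      o[rr, ci] <- p %*% v[rr, ci, drop = FALSE]
    }
  }
  y <- sweep(o %*% wo$val, 2L, as.numeric(bo$val), `+`)
  nd <- adNode(y, list(x, wq, bq, wk, bk, wv, bv, wo, bo), NULL, req = TRUE)
  nd$q <- q; nd$k <- k; nd$v <- v; nd$o <- o; nd$plist <- plist
  nd$tt <- tt; nd$n_heads <- n_heads; nd$n_slices <- n_slices
  nd$backward <- function(nd) {
    g <- nd$grad
    d <- ncol(nd$q)
    dh <- d %/% nd$n_heads
    wo_ <- nd$parents[[8]]$val
    dwo <- crossprod(nd$o, g)
    dbo <- matrix(colSums(g), nrow = 1)
    do_ <- tcrossprod(g, wo_)
    dq <- matrix(0, nrow(nd$q), d)
    dk <- dq
    dv <- dq
    for (s in seq_len(nd$n_slices)) {
      rr <- ((s - 1L) * nd$tt + 1L):(s * nd$tt)
      for (h in seq_len(nd$n_heads)) {
        ci <- ((h - 1L) * dh + 1L):(h * dh)
        p <- nd$plist[[(s - 1L) * nd$n_heads + h]]
        dp <- tcrossprod(do_[rr, ci, drop = FALSE], nd$v[rr, ci, drop = FALSE])
        dv[rr, ci] <- crossprod(p, do_[rr, ci, drop = FALSE])
        ds <- p * (dp - rowSums(dp * p)) / sqrt(dh)
        dq[rr, ci] <- ds %*% nd$k[rr, ci, drop = FALSE]
        dk[rr, ci] <- crossprod(ds, nd$q[rr, ci, drop = FALSE])
      }
    }
    x_ <- nd$parents[[1]]$val
    wq_ <- nd$parents[[2]]$val
    wk_ <- nd$parents[[4]]$val
    wv_ <- nd$parents[[6]]$val
    dx <- tcrossprod(dq, wq_) + tcrossprod(dk, wk_) + tcrossprod(dv, wv_)
    list(dx,
         crossprod(x_, dq), matrix(colSums(dq), nrow = 1),
         crossprod(x_, dk), matrix(colSums(dk), nrow = 1),
         crossprod(x_, dv), matrix(colSums(dv), nrow = 1),
         dwo, dbo)
  }
  nd
}

# Mean over each slice's token block: (n_slices*t) x d -> n_slices x d.
adPoolSlices <- function(a, tokens_per_slice) {
  tt <- tokens_per_slice
  n_rows <- nrow(a$val)
  stopifnot(n_rows %% tt == 0L)
  grp <- rep(seq_len(n_rows %/% tt), each = tt)
  y <- rowsum(a$val, grp, reorder = FALSE) / tt
  adNode(y, list(a), local({
    t_ <- tt
    function(nd) {
      list(nd$grad[rep(seq_len(nrow(nd$grad)), each = t_), , drop = FALSE] / t_)
    }
  }), req = a$req)
}

# Add a (t x d) parameter tile to each slice's token block.
adAddTile <- function(a, p, times) {
  y <- a$val + do.call(rbind, rep(list(p$val), times))
  adNode(y, list(a, p), local({
    k <- times
    tp <- nrow(p$val)
    function(nd) {
      g <- nd$grad
      gp <- rowsum(g, rep(seq_len(tp), k), reorder = FALSE)
      list(g, gp)
    }
  }), req = a$req || p$req)
}
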