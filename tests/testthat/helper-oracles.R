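# Independent reference implementations used as oracles.  These are
# deliberately naive (explicit loops, exhaustive enumeration) and share no
# code with the package internals.

# Single-instance multi-head attention by explicit loops: per-head
# projection, pairwise dot products, softmax, weighted sum, concatenation,
# output projection.
oracleAttention <- function(q, k, v, params, nHeads) {
  d <- ncol(q)
  dh <- d / nHeads
  lin <- function(x, w, b) {
    out <- matrix(0, nrow(x), ncol(w))
    for (i in seq_len(nrow(x)))
      for (j in seq_len(ncol(w)))
        out[i, j] <- sum(x[i, ] * w[, j]) + b[j]
    out
  }
  qp <- lin(q, params$wq, as.numeric(params$bq))
  kp <- lin(k, params$wk, as.numeric(params$bk))
  vp <- lin(v, params$wv, as.numeric(params$bv))
  heads <- matrix(0, nrow(q), d)
  for (h in seq_len(nHeads)) {
    ci <- ((h - 1) * dh + 1):(h * dh)
    for (i in seq_len(nrow(q))) {
      sc <- numeric(nrow(k))
      for (j in seq_len(nrow(k)))
        sc[j] <- sum(qp[i, ci] * kp[j, ci]) / sqrt(dh)
      w <- exp(sc - max(sc))
      w <- w / sum(w)
      acc <- numeric(dh)
      for (j in seq_len(nrow(k))) acc <- acc + w[j] * vp[j, ci]
      heads[i, ci] <- acc
    }
  }
  lin(heads, params$wo, as.numeric(params$bo))
}

# Two-layer scoring MLP by per-row loops (same architecture as Phi).
oraclePhi <- function(features, params) {
  out <- matrix(0, nrow(features), ncol(params$ph2.w))
  gelu <- function(x) x * pnorm(x)
  for (i in seq_len(nrow(features))) {
    h <- gelu(as.numeric(features[i, ] %*% params$ph1.w) +
                as.numeric(params$ph1.b))
    out[i, ] <- as.numeric(h %*% params$ph2.w) + as.numeric(params$ph2.b)
  }
  out
}

# Brute-force FSA: enumerate every M-subset, score by summed per-node max
# score, break ties lexicographically by positions (smallest first).
oracleTopM <- function(scores, M) {
  n <- length(scores)
  subsets <- utils::combn(n, M)
  best <- NULL
  bestSum <- -Inf
  for (c_ in seq_len(ncol(subsets))) {
    s <- subsets[, c_]
    tot <- sum(scores[s])
    if (tot > bestSum + 1e-12) {
      bestSum <- tot
      best <- s
    }
    # combn emits subsets in lexicographic order, so the first subset
    # achieving the maximum already has the smallest positions
  }
  best
}

# Three-layer edge MLP applied pair by pair.
oracleDenseAdjacency <- function(features, params) {
  n <- nrow(features)
  gelu <- function(x) x * pnorm(x)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    g <- c(features[i, ], features[j, ],
           sum((features[i, ] - features[j, ])^2))
    h1 <- gelu(as.numeric(g %*% params$om1.w) + as.numeric(params$om1.b))
    h2 <- gelu(as.numeric(h1 %*% params$om2.w) + as.numeric(params$om2.b))
    S[i, j] <- as.numeric(h2 %*% params$om3.w) + as.numeric(params$om3.b)
  }
  S
}

# Residual GCN block by per-node loops.
oracleGcnBlock <- function(features, A, params, normalize = "row") {
  n <- nrow(features)
  d <- ncol(features)
  gelu <- function(x) x * pnorm(x)
  ln <- function(x, g, b) {
    mu <- mean(x)
    sd_ <- sqrt(mean((x - mu)^2) + 1e-5)
    ((x - mu) / sd_) * as.numeric(g) + as.numeric(b)
  }
  A <- as.matrix(A)
  xl <- t(vapply(seq_len(n), function(i)
    ln(features[i, ], params$lnin.g, params$lnin.b), numeric(d)))
  out <- matrix(0, n, d)
  for (i in seq_len(n)) {
    agg <- numeric(d)
    for (j in seq_len(n)) agg <- agg + A[i, j] * xl[j, ]
    if (normalize == "row") agg <- agg / max(1, sum(A[i, ] != 0))
    gm <- gelu(ln(agg, params$lng.g, params$lng.b))
    out[i, ] <- as.numeric(gm %*% params$w) + features[i, ]
  }
  out
}

# AUC as the fraction of concordant positive/negative pairs (ties 1/2).
oracleAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

randIndicators <- function() runif(14)
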