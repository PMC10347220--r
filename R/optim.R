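# AdamW: Adam moment estimates with decoupled weight decay.  Weight decay
# is applied to weight matrices only, not to biases, layer-norm affines or
# the positional embedding (the usual transformer convention).
#
# For speed the parameter list is flattened once into a single numeric
# vector; moment updates are then a handful of vectorized operations.

.decayedParam <- function(name) grepl("\\.(w|w1|w2|wq|wk|wv|wo)$", name)

.paramSkeleton <- function(params) {
  dims <- lapply(params, dim)
  lens <- vapply(params, length, 0L)
  offs <- cumsum(c(0L, lens[-length(lens)]))
  names(offs) <- names(params)
  decay <- rep(vapply(names(params), .decayedParam, TRUE), times = lens)
  list(dims = dims, lens = lens, offs = offs, decay = decay)
}

.unflattenParams <- function(vec, skel) {
  out <- vector("list", length(skel$lens))
  names(out) <- names(skel$lens)
  for (nm in names(out)) {
    o <- skel$offs[[nm]]
    out[[nm]] <- array(vec[(o + 1L):(o + skel$lens[[nm]])], skel$dims[[nm]])
  }
  out
}

adamwInit <- function(params) {
  skel <- .paramSkeleton(params)
  n <- sum(skel$lens)
  list(skel = skel, m = numeric(n), v = numeric(n), t = 0L)
}

adamwStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weightDecay = 0.01, clipNorm = Inf) {
  skel <- state$skel
  p <- unlist(params[names(skel$lens)], use.names = FALSE)
  g <- unlist(grads[names(skel$lens)], use.names = FALSE)
  if (is.finite(clipNorm)) {
    gn <- sqrt(sum(g * g))
    if (gn > clipNorm) g <- g * (clipNorm / gn)
  }
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g * g
  upd <- (state$m / (1 - beta1^state$t)) /
    (sqrt(state$v / (1 - beta2^state$t)) + eps)
  if (weightDecay > 0) upd <- upd + weightDecay * skel$decay * p
  list(params = .unflattenParams(p - lr * upd, skel), state = state)
}
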