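# Minimal neural-network primitives: a batched one-layer LSTM with full
# backpropagation through time, dense layers, and the Adamax optimizer.
# Everything operates on plain numeric matrices; sentences of identical shape
# are processed as a batch (rows = sentences).

sigmoid <- function(x) 1 / (1 + exp(-x))

# uniform init in [-1/sqrt(fan_in), 1/sqrt(fan_in)]
init_linear <- function(fan_in, fan_out) {
  k <- 1 / sqrt(fan_in)
  matrix(stats::runif(fan_in * fan_out, -k, k), fan_in, fan_out)
}

init_lstm <- function(input_size, hidden_size) {
  k <- 1 / sqrt(hidden_size)
  list(Wx = matrix(stats::runif(input_size * 4 * hidden_size, -k, k),
                   input_size, 4 * hidden_size),
       Wh = matrix(stats::runif(hidden_size * 4 * hidden_size, -k, k),
                   hidden_size, 4 * hidden_size),
       b = stats::runif(4 * hidden_size, -k, k))
}

# Forward pass over a batch of equal-length id sequences.
#   E: V x D embedding matrix; lstm: list(Wx, Wh, b); ids: B x T matrix of
#   1-based row indices into E. Returns per-step hidden/cell states and gate
#   caches needed for backprop. Initial state is the zero vector.
lstm_forward <- function(E, lstm, ids) {
  B <- nrow(ids); Tn <- ncol(ids); H <- ncol(lstm$Wh) / 4L
  h <- matrix(0, B, H); c <- matrix(0, B, H)
  Hs <- vector("list", Tn); Cs <- vector("list", Tn); cache <- vector("list", Tn)
  iH <- seq_len(H); iF <- H + iH; iG <- 2L * H + iH; iO <- 3L * H + iH
  for (t in seq_len(Tn)) {
    X <- E[ids[, t], , drop = FALSE]
    Z <- X %*% lstm$Wx + h %*% lstm$Wh
    Z <- sweep(Z, 2L, lstm$b, "+")
    gi <- sigmoid(Z[, iH, drop = FALSE])
    gf <- sigmoid(Z[, iF, drop = FALSE])
    gg <- tanh(Z[, iG, drop = FALSE])
    go <- sigmoid(Z[, iO, drop = FALSE])
    c_new <- gf * c + gi * gg
    tC <- tanh(c_new)
    h_new <- go * tC
    cache[[t]] <- list(X = X, h_prev = h, c_prev = c,
                       i = gi, f = gf, g = gg, o = go, tC = tC)
    h <- h_new; c <- c_new
    Hs[[t]] <- h; Cs[[t]] <- c
  }
  list(H = Hs, C = Cs, cache = cache)
}

# Backward pass. dH_ext: list (length T) of B x H matrices with the external
# gradient arriving at each hidden state (or NULL for zero). Returns gradients
# for the LSTM weights and the embedding matrix (dense V x D).
lstm_backward <- function(E, lstm, ids, fw, dH_ext) {
  B <- nrow(ids); Tn <- ncol(ids); H <- ncol(lstm$Wh) / 4L
  dWx <- matrix(0, nrow(lstm$Wx), ncol(lstm$Wx))
  dWh <- matrix(0, nrow(lstm$Wh), ncol(lstm$Wh))
  db <- numeric(length(lstm$b))
  dE <- matrix(0, nrow(E), ncol(E))
  dh <- matrix(0, B, H); dc <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    ca <- fw$cache[[t]]
    if (!is.null(dH_ext[[t]])) dh <- dh + dH_ext[[t]]
    do_ <- dh * ca$tC
    dc <- dc + dh * ca$o * (1 - ca$tC^2)
    df <- dc * ca$c_prev
    di <- dc * ca$g
    dg <- dc * ca$i
    dZ <- cbind(di * ca$i * (1 - ca$i),
                df * ca$f * (1 - ca$f),
                dg * (1 - ca$g^2),
                do_ * ca$o * (1 - ca$o))
    dWx <- dWx + crossprod(ca$X, dZ)
    dWh <- dWh + crossprod(ca$h_prev, dZ)
    db <- db + colSums(dZ)
    dX <- dZ %*% t(lstm$Wx)
    agg <- rowsum(dX, group = ids[, t])
    ridx <- as.integer(rownames(agg))
    dE[ridx, ] <- dE[ridx, , drop = FALSE] + agg
    dh <- dZ %*% t(lstm$Wh)
    dc <- dc * ca$f
  }
  list(Wx = dWx, Wh = dWh, b = db, E = dE)
}

# ---- Adamax -----------------------------------------------------------------
# m_t = b1 m + (1-b1) g ; u_t = max(b2 u, |g|) ;
# theta -= lr/(1-b1^t) * m_t / (u_t + eps)

adamax_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), u = zero_like(params), step = 0L)
}

adamax_step <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  corr <- lr / (1 - beta1^state$step)
  upd <- function(p, g, m, u) {
    if (is.list(p)) {
      out <- lapply(names(p), function(nm)
        upd(p[[nm]], g[[nm]], m[[nm]], u[[nm]]))
      names(out) <- names(p)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  u = lapply(out, `[[`, "u")))
    }
    m <- beta1 * m + (1 - beta1) * g
    u <- pmax(beta2 * u, abs(g))
    list(p = p - corr * m / (u + eps), m = m, u = u)
  }
  out <- upd(params, grads, state$m, state$u)
  list(params = out$p, state = list(m = out$m, u = out$u, step = state$step))
}

# elementwise sum of two parameter trees (gradient accumulation); matched
# by name so construction order does not matter
tree_add <- function(a, b) {
  if (is.list(a)) {
    out <- lapply(names(a), function(nm) tree_add(a[[nm]], b[[nm]]))
    names(out) <- names(a)
    return(out)
  }
  a + b
}

tree_scale <- function(a, s) {
  if (is.list(a)) return(lapply(a, tree_scale, s = s))
  a * s
}
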