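# Independent dense reference implementations used as oracles. These are
# deliberately written as plain elementwise loops, sharing no code with the
# package internals they check.

sigmoid_ref <- function(z) 1 / (1 + exp(-z))

# Channel attention by explicit loops over channels and batch items.
channel_attention_ref <- function(x, W1, W2) {
  d <- dim(x)
  C <- d[3]; B <- d[4]
  out <- matrix(0, C, B)
  for (b in seq_len(B)) {
    avg <- numeric(C); mx <- numeric(C)
    for (c in seq_len(C)) {
      sl <- x[, , c, b]
      avg[c] <- mean(sl)
      mx[c] <- max(sl)
    }
    mlp <- function(v) as.numeric(W2 %*% pmax(W1 %*% v, 0))
    out[, b] <- sigmoid_ref(mlp(avg) + mlp(mx))
  }
  out
}

# Spatial attention: per-pixel channel mean/max, k x k conv (pad (k-1)/2),
# sigmoid; explicit quadruple loop convolution.
spatial_attention_ref <- function(xhat, Wsp, bsp) {
  d <- dim(xhat)
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  k <- dim(Wsp)[1]
  pad <- (k - 1) %/% 2
  out <- array(0, c(H, W, 1, B))
  for (b in seq_len(B)) {
    mmean <- apply(xhat[, , , b, drop = FALSE], c(1, 2), mean)
    mmax <- apply(xhat[, , , b, drop = FALSE], c(1, 2), max)
    maps <- list(mmean, mmax)
    for (oh in seq_len(H)) for (ow in seq_len(W)) {
      acc <- bsp
      for (i in seq_len(k)) for (j in seq_len(k)) for (ch in 1:2) {
        hi <- oh + i - 1 - pad
        wi <- ow + j - 1 - pad
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
          acc <- acc + maps[[ch]][hi, wi] * Wsp[i, j, ch, 1]
      }
      out[oh, ow, 1, b] <- sigmoid_ref(acc)
    }
  }
  out
}

softmax_ref <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

# One attention head by explicit row loops.
attention_head_ref <- function(Q, K, V, d) {
  C <- nrow(Q)
  out <- matrix(0, C, ncol(V))
  for (r in seq_len(C)) {
    logits <- as.numeric(K %*% Q[r, ]) / sqrt(d)
    w <- softmax_ref(logits)
    out[r, ] <- colSums(V * w)
  }
  out
}

# Full MGCA block on one sample: per-head projections, attention, concat,
# output projection, Hadamard gate + residual.
mgca_block_ref <- function(F3, Tp, params) {
  n <- params$buf$n_heads
  d <- params$buf$d
  E <- params$buf$E
  cat <- NULL
  for (i in seq_len(n)) {
    Q <- F3 %*% params$par[[paste0("Wq", i)]]
    K <- Tp %*% params$par[[paste0("Wk", i)]]
    V <- Tp %*% params$par[[paste0("Wv", i)]]
    cat <- cbind(cat, attention_head_ref(Q, K, V, d))
  }
  A <- sweep(cat %*% params$par$Wo, 2, params$par$bo, `+`)
  list(A = A, F3_prime = A * F3 + F3)
}

# Harmonic-rank voting by brute-force accumulation.
vote_ref <- function(ranks, w, k) {
  nf <- ncol(ranks)
  v <- numeric(nf)
  for (f in seq_len(nf))
    for (m in seq_len(nrow(ranks)))
      v[f] <- v[f] + w[m] / ranks[m, f]
  s <- v / sum(v)
  names(s) <- colnames(ranks)
  list(votes = v, scores = s,
       selected = colnames(ranks)[order(-s)][seq_len(k)])
}

rand_map <- function(H, W, C, B) array(rnorm(H * W * C * B), c(H, W, C, B))
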