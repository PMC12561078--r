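# Meta-Guided Cross-Attention (MGCA).
#
# Image tokens F3 (C x E per sample) query text-derived keys/values
# (L x E per sample) through multi-head scaled dot-product cross-attention:
#   Q_i = F3 W_Q^i,  K_i = T' W_K^i,  V_i = T' W_V^i      (d = E / n_heads)
#   CA_i = softmax(Q_i K_i^T / sqrt(d)) V_i               (softmax over L)
#   A = concat(CA_1..CA_n) W_O + b_O
#   F3' = (A * F3) + F3                                   (Hadamard gate)
# The fused delta A * F3 is mapped back to the stage-4 spatial grid by the
# transpose of the token projection, so a zeroed output projection leaves
# the image stream bit-exactly unchanged (the "no fusion" mechanism).

#' Construct MGCA fusion parameters
#'
#' @param embed_dim shared embedding dimension `E` (divisible by `n_heads`).
#' @param n_heads number of attention heads (default 4; 1/2/4/8 all valid).
#' @param hw number of spatial positions of the stage-3 grid (`H*W`), used
#'   for the token projection.
#' @param attn_scale `"sqrt"` (default) scales logits by `1/sqrt(d)`;
#'   `"linear"` uses `1/d`, the literal typeset reading.
#' @return `fusion_params` layer object.
#' @export
mgca_layer <- function(embed_dim, n_heads = 4, hw, attn_scale = "sqrt") {
  if (embed_dim %% n_heads != 0)
    nn_stop("construction_error",
            "embed_dim (%d) must be divisible by n_heads (%d)",
            embed_dim, n_heads)
  d <- embed_dim %/% n_heads
  par <- list(Wtok = matrix(rnorm(hw * embed_dim, sd = sqrt(1 / hw)),
                            hw, embed_dim))
  for (i in seq_len(n_heads)) {
    sdp <- sqrt(1 / embed_dim)
    par[[paste0("Wq", i)]] <- matrix(rnorm(embed_dim * d, sd = sdp), embed_dim, d)
    par[[paste0("Wk", i)]] <- matrix(rnorm(embed_dim * d, sd = sdp), embed_dim, d)
    par[[paste0("Wv", i)]] <- matrix(rnorm(embed_dim * d, sd = sdp), embed_dim, d)
  }
  par$Wo <- matrix(rnorm(embed_dim * embed_dim, sd = sqrt(1 / embed_dim)),
                   embed_dim, embed_dim)
  par$bo <- numeric(embed_dim)
  ly <- new_layer("mgca", par = par,
                  buf = list(E = as.integer(embed_dim),
                             n_heads = as.integer(n_heads),
                             d = as.integer(d), hw = as.integer(hw),
                             attn_scale = attn_scale))
  class(ly) <- c("fusion_params", class(ly))
  ly
}

attn_scale_factor <- function(ly) {
  if (ly$buf$attn_scale == "linear") 1 / ly$buf$d else 1 / sqrt(ly$buf$d)
}

#' Per-head query/key/value projections
#'
#' Queries come from the image tokens, keys and values from the projected
#' text features (never swapped).
#'
#' @param F3 image tokens `(C, E, B)`.
#' @param T_prime projected text features `(L, E, B)`.
#' @param params a `fusion_params` object.
#' @param head head index in `1..n_heads`.
#' @return list with `Q` `(C, d, B)`, `K` and `V` `(L, d, B)`.
#' @export
project_qkv <- function(F3, T_prime, params, head) {
  stopifnot(head >= 1, head <= params$buf$n_heads)
  dF <- dim(F3); dT <- dim(T_prime)
  d <- params$buf$d
  Q <- array(0, c(dF[1], d, dF[3]))
  K <- array(0, c(dT[1], d, dT[3]))
  V <- array(0, c(dT[1], d, dT[3]))
  for (b in seq_len(dF[3])) {
    Q[, , b] <- matrix(F3[, , b], dF[1], dF[2]) %*% params$par[[paste0("Wq", head)]]
    Tb <- matrix(T_prime[, , b], dT[1], dT[2])
    K[, , b] <- Tb %*% params$par[[paste0("Wk", head)]]
    V[, , b] <- Tb %*% params$par[[paste0("Wv", head)]]
  }
  list(Q = Q, K = K, V = V)
}

#' One cross-attention head
#'
#' `CA = softmax(Q K^T * scale) V` with the softmax over the text axis, so
#' each attention row is a convex combination of value rows.
#'
#' @param Q `(C, d, B)` queries.
#' @param K,V `(L, d, B)` keys and values.
#' @param d head dimension (scale denominator `sqrt(d)`).
#' @return `(C, d, B)` attention output.
#' @export
cross_attention_head <- function(Q, K, V, d = dim(Q)[2]) {
  dq <- dim(Q); dk <- dim(K)
  out <- array(0, c(dq[1], dq[2], dq[3]))
  for (b in seq_len(dq[3])) {
    S <- (matrix(Q[, , b], dq[1], dq[2]) %*%
            t(matrix(K[, , b], dk[1], dk[2]))) / sqrt(d)
    P <- softmax_rows(S)
    out[, , b] <- P %*% matrix(V[, , b], dk[1], dk[2])
  }
  out
}

#' Full MGCA fusion block
#'
#' Runs all heads, concatenates, applies the output projection, gates the
#' image tokens (`A * F3`) and adds the residual.
#'
#' @param F3 image tokens `(C, E, B)`.
#' @param T_prime projected text features `(L, E, B)`.
#' @param params a `fusion_params` object.
#' @return list with `A` (attention output `(C, E, B)`), `F3_prime`
#'   (fused tokens `(A * F3) + F3`) and `delta` (`A * F3`, the increment the
#'   backbone re-injects spatially).
#' @export
fuse <- function(F3, T_prime, params) {
  dF <- dim(F3); dT <- dim(T_prime)
  n <- params$buf$n_heads; d <- params$buf$d; E <- params$buf$E
  scale <- attn_scale_factor(params)
  A <- array(0, c(dF[1], E, dF[3]))
  for (b in seq_len(dF[3])) {
    Fb <- matrix(F3[, , b], dF[1], dF[2])
    Tb <- matrix(T_prime[, , b], dT[1], dT[2])
    cat <- matrix(0, dF[1], E)
    for (i in seq_len(n)) {
      Qi <- Fb %*% params$par[[paste0("Wq", i)]]
      Ki <- Tb %*% params$par[[paste0("Wk", i)]]
      Vi <- Tb %*% params$par[[paste0("Wv", i)]]
      P <- softmax_rows(Qi %*% t(Ki) * scale)
      cat[, (i - 1) * d + seq_len(d)] <- P %*% Vi
    }
    A[, , b] <- sweep(cat %*% params$par$Wo, 2, params$par$bo, `+`)
  }
  delta <- A * F3
  list(A = A, F3_prime = delta + F3, delta = delta)
}

## ---- trainable forward/backward -------------------------------------------

# Forward through token projection + MGCA + spatial re-injection.
# x: stage-3 feature map (H, W, C, B); Tp: projected text (L, E, B).
# Returns the stage-4 input feature map; caches everything for backward.
mgca_fwd <- function(ly, x, Tp) {
  dx <- dim(x)
  HW <- dx[1] * dx[2]; C <- dx[3]; B <- dx[4]
  E <- ly$buf$E; n <- ly$buf$n_heads; d <- ly$buf$d
  scale <- attn_scale_factor(ly)
  out <- x
  cache <- vector("list", B)
  for (b in seq_len(B)) {
    Fmat <- t(matrix(x[, , , b], nrow = HW))          # C x HW
    tok <- Fmat %*% ly$par$Wtok                       # C x E
    Tb <- matrix(Tp[, , b], dim(Tp)[1], E)
    heads <- vector("list", n)
    cat <- matrix(0, C, E)
    for (i in seq_len(n)) {
      Qi <- tok %*% ly$par[[paste0("Wq", i)]]
      Ki <- Tb %*% ly$par[[paste0("Wk", i)]]
      Vi <- Tb %*% ly$par[[paste0("Wv", i)]]
      P <- softmax_rows(Qi %*% t(Ki) * scale)
      heads[[i]] <- list(Q = Qi, K = Ki, V = Vi, P = P)
      cat[, (i - 1) * d + seq_len(d)] <- P %*% Vi
    }
    A <- sweep(cat %*% ly$par$Wo, 2, ly$par$bo, `+`)  # C x E
    G <- A * tok                                      # gated delta in token space
    delta <- G %*% t(ly$par$Wtok)                     # C x HW
    out[, , , b] <- x[, , , b] + array(t(delta), dx[1:3])
    cache[[b]] <- list(Fmat = Fmat, tok = tok, Tb = Tb, heads = heads,
                       cat = cat, A = A, G = G)
  }
  ly$cache <- list(per = cache, dx = dx, dT = dim(Tp))
  out
}

# dy: gradient at the stage-4 input. Returns list(dx, dTp).
mgca_bwd <- function(ly, dy) {
  cc <- ly$cache
  dxdim <- cc$dx
  HW <- dxdim[1] * dxdim[2]; C <- dxdim[3]; B <- dxdim[4]
  E <- ly$buf$E; n <- ly$buf$n_heads; d <- ly$buf$d
  scale <- attn_scale_factor(ly)
  dx <- dy                                            # identity path
  dTp <- array(0, cc$dT)
  for (b in seq_len(B)) {
    pb <- cc$per[[b]]
    ddelta <- t(matrix(dy[, , , b], nrow = HW))       # C x HW
    dG <- ddelta %*% ly$par$Wtok                      # C x E
    ly$grad$Wtok <- ly$grad$Wtok + t(ddelta) %*% pb$G
    dA <- dG * pb$tok
    dtok <- dG * pb$A
    dcat <- dA %*% t(ly$par$Wo)
    ly$grad$Wo <- ly$grad$Wo + t(pb$cat) %*% dA
    ly$grad$bo <- ly$grad$bo + colSums(dA)
    dTb <- matrix(0, nrow(pb$Tb), E)
    for (i in seq_len(n)) {
      hd <- pb$heads[[i]]
      dCA <- dcat[, (i - 1) * d + seq_len(d), drop = FALSE]
      dP <- dCA %*% t(hd$V)
      dV <- t(hd$P) %*% dCA
      dS <- softmax_rows_bwd(hd$P, dP) * scale
      dQ <- dS %*% hd$K
      dK <- t(dS) %*% hd$Q
      ly$grad[[paste0("Wq", i)]] <- ly$grad[[paste0("Wq", i)]] + t(pb$tok) %*% dQ
      ly$grad[[paste0("Wk", i)]] <- ly$grad[[paste0("Wk", i)]] + t(pb$Tb) %*% dK
      ly$grad[[paste0("Wv", i)]] <- ly$grad[[paste0("Wv", i)]] + t(pb$Tb) %*% dV
      dtok <- dtok + dQ %*% t(ly$par[[paste0("Wq", i)]])
      dTb <- dTb + dK %*% t(ly$par[[paste0("Wk", i)]]) +
        dV %*% t(ly$par[[paste0("Wv", i)]])
    }
    # tok = Fmat %*% Wtok
    ly$grad$Wtok <- ly$grad$Wtok + t(pb$Fmat) %*% dtok
    dFmat <- dtok %*% t(ly$par$Wtok)                  # C x HW
    dx[, , , b] <- dx[, , , b] + array(t(dFmat), dxdim[1:3])
    dTp[, , b] <- dTb
  }
  list(dx = dx, dTp = dTp)
}
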