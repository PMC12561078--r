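# Convolutional Block Attention Module (CBAM).
#
# Channel attention: ChA = sigmoid(MLP(avgpool(O0)) + MLP(maxpool(O0))), one
# weight per channel, with the bottleneck MLP shared between the two pooling
# branches. Spatial attention: the channel-gated map O^0 = O0 * ChA is
# reduced to per-pixel channel mean and max, the two maps are concatenated
# and convolved (k x k, 2 -> 1 channels), and a sigmoid gives SpA. The
# refined output is O0' = SpA * O^0.

#' Construct CBAM parameters
#'
#' @param channels number of input channels.
#' @param reduction bottleneck reduction ratio of the shared MLP (default 16;
#'   must divide `channels`).
#' @param spatial_kernel side of the spatial convolution kernel (default 7,
#'   padding `(k-1)/2`).
#' @return a `cbam_params` layer object.
#' @export
cbam_layer <- function(channels, reduction = 16, spatial_kernel = 7) {
  if (channels %% reduction != 0)
    nn_stop("construction_error",
            "channels (%d) must be divisible by reduction (%d)",
            channels, reduction)
  cr <- channels %/% reduction
  pad <- (spatial_kernel - 1) %/% 2
  ly <- new_layer("cbam",
                  par = list(
                    W1 = matrix(rnorm(cr * channels, sd = sqrt(2 / channels)),
                                cr, channels),
                    W2 = matrix(rnorm(channels * cr, sd = sqrt(2 / cr)),
                                channels, cr),
                    Wsp = array(rnorm(spatial_kernel^2 * 2,
                                      sd = sqrt(2 / (2 * spatial_kernel^2))),
                                dim = c(spatial_kernel, spatial_kernel, 2, 1)),
                    bsp = 0),
                  buf = list(channels = channels, reduction = reduction,
                             spatial_kernel = spatial_kernel, pad = pad))
  class(ly) <- c("cbam_params", class(ly))
  ly
}

# channel-broadcast multiply: v is (C x B)
mul_channel <- function(x, v) {
  HW <- dim(x)[1] * dim(x)[2]
  x * rep(as.vector(v), each = HW)
}

# spatial-broadcast multiply: S is (HW x B)
mul_spatial <- function(x, S) {
  d <- dim(x)
  C <- d[3]; B <- d[4]
  x * as.vector(S[, rep(seq_len(B), each = C), drop = FALSE])
}

# global average and max pooling over the spatial grid -> (C x B) each
pool_spatial <- function(x) {
  d <- dim(x)
  HW <- d[1] * d[2]; C <- d[3]; B <- d[4]
  M <- matrix(x, nrow = HW)
  avg <- matrix(colMeans(M), C, B)
  am <- max.col(t(M), ties.method = "first")
  mx <- matrix(M[cbind(am, seq_len(C * B))], C, B)
  list(avg = avg, mx = mx, argmax = am, M = M)
}

cbam_mlp <- function(ly, P) {
  H <- pmax(ly$par$W1 %*% P, 0)
  list(out = ly$par$W2 %*% H, hidden = H)
}

#' Channel attention weights
#'
#' @param O0 feature map array `(H, W, C, B)`.
#' @param params a `cbam_params` object.
#' @return `(C x B)` matrix of per-channel sigmoid gates, entries in (0, 1).
#' @export
channel_attention <- function(O0, params) {
  p <- pool_spatial(O0)
  z <- cbam_mlp(params, p$avg)$out + cbam_mlp(params, p$mx)$out
  1 / (1 + exp(-z))
}

#' Spatial attention map
#'
#' @param O_hat channel-gated feature map `(H, W, C, B)` (i.e. `O0 * ChA`).
#' @param params a `cbam_params` object.
#' @return `(H, W, 1, B)` array of sigmoid gates, entries in (0, 1).
#' @export
spatial_attention <- function(O_hat, params) {
  d <- dim(O_hat)
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  A3 <- array(O_hat, c(H * W, C, B))
  cat2 <- array(0, c(H, W, 2, B))
  for (b in seq_len(B)) {
    slab <- A3[, , b, drop = TRUE]
    if (C == 1) slab <- matrix(slab, ncol = 1)
    cat2[, , 1, b] <- rowMeans(slab)
    mc <- max.col(slab, ties.method = "first")
    cat2[, , 2, b] <- slab[cbind(seq_len(H * W), mc)]
  }
  z <- conv2d_fwd_cpp(cat2, params$par$Wsp, params$par$bsp, 1L, params$buf$pad)
  1 / (1 + exp(-z))
}

#' CBAM refinement
#'
#' `O0' = SpA * (O0 * ChA)`: channel gating followed by spatial gating;
#' output has the shape of the input.
#'
#' @param O0 feature map array `(H, W, C, B)`.
#' @param params a `cbam_params` object.
#' @return refined array, same shape as `O0`.
#' @export
cbam_refine <- function(O0, params) {
  ChA <- channel_attention(O0, params)
  Ohat <- mul_channel(O0, ChA)
  SpA <- spatial_attention(Ohat, params)
  d <- dim(O0)
  mul_spatial(Ohat, matrix(SpA, d[1] * d[2], d[4]))
}

## ---- trainable forward/backward -------------------------------------------

cbam_fwd <- function(ly, x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  HW <- H * W
  p <- pool_spatial(x)
  ma <- cbam_mlp(ly, p$avg)
  mm <- cbam_mlp(ly, p$mx)
  ChA <- 1 / (1 + exp(-(ma$out + mm$out)))          # C x B
  xhat <- mul_channel(x, ChA)
  A3 <- array(xhat, c(HW, C, B))
  cat2 <- array(0, c(H, W, 2, B))
  argc <- matrix(0L, HW, B)
  for (b in seq_len(B)) {
    slab <- A3[, , b, drop = TRUE]
    if (C == 1) slab <- matrix(slab, ncol = 1)
    cat2[, , 1, b] <- rowMeans(slab)
    mc <- max.col(slab, ties.method = "first")
    argc[, b] <- mc
    cat2[, , 2, b] <- slab[cbind(seq_len(HW), mc)]
  }
  zsp <- conv2d_fwd_cpp(cat2, ly$par$Wsp, ly$par$bsp, 1L, ly$buf$pad)
  SpA <- 1 / (1 + exp(-zsp))                        # H x W x 1 x B
  Smat <- matrix(SpA, HW, B)
  out <- mul_spatial(xhat, Smat)
  ly$cache <- list(x = x, dims = d, pool = p, ma = ma, mm = mm, ChA = ChA,
                   xhat = xhat, cat2 = cat2, SpA = Smat, argc = argc)
  out
}

cbam_bwd <- function(ly, dy) {
  cc <- ly$cache
  d <- cc$dims
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  HW <- H * W
  # out = xhat * SpA (spatial broadcast)
  expS <- as.vector(cc$SpA[, rep(seq_len(B), each = C), drop = FALSE])
  dxhat <- dy * expS
  A3 <- array(cc$xhat, c(HW, C, B))
  D3 <- array(dy, c(HW, C, B))
  dS <- matrix(0, HW, B)
  for (b in seq_len(B)) {
    slab <- A3[, , b, drop = TRUE]
    if (C == 1) slab <- matrix(slab, ncol = 1)
    dslab <- D3[, , b, drop = TRUE]
    if (C == 1) dslab <- matrix(dslab, ncol = 1)
    dS[, b] <- rowSums(dslab * slab)
  }
  # SpA = sigmoid(conv(cat2))
  dz <- array(dS * (cc$SpA * (1 - cc$SpA)), c(H, W, 1, B))
  r <- conv2d_bwd_cpp(cc$cat2, ly$par$Wsp, dz, 1L, ly$buf$pad)
  ly$grad$Wsp <- ly$grad$Wsp + r$dw
  ly$grad$bsp <- ly$grad$bsp + r$db
  dcat <- r$dx                                      # H x W x 2 x B
  dmean <- array(dcat[, , 1, ], c(HW, B))
  dmax <- array(dcat[, , 2, ], c(HW, B))
  dxhat3 <- array(dxhat, c(HW, C, B))
  for (b in seq_len(B)) {
    dxhat3[, , b] <- dxhat3[, , b] + dmean[, b] / C
    idx <- cbind(seq_len(HW), cc$argc[, b])
    slab <- dxhat3[, , b, drop = TRUE]
    if (C == 1) slab <- matrix(slab, ncol = 1)
    slab[idx] <- slab[idx] + dmax[, b]
    dxhat3[, , b] <- slab
  }
  dxhat <- array(dxhat3, d)
  # xhat = x * ChA (channel broadcast)
  Dm <- matrix(dxhat, nrow = HW)
  Xm <- matrix(cc$x, nrow = HW)
  dChA <- matrix(colSums(Dm * Xm), C, B)
  dx <- mul_channel(dxhat, cc$ChA)
  # ChA = sigmoid(MLP(avg) + MLP(max)), shared MLP weights
  dzc <- dChA * cc$ChA * (1 - cc$ChA)               # C x B
  davg <- cbam_mlp_bwd(ly, dzc, cc$ma, cc$pool$avg)
  dmx <- cbam_mlp_bwd(ly, dzc, cc$mm, cc$pool$mx)
  # avg pool: uniform spread; max pool: route to spatial argmax
  dx <- dx + array(rep(as.vector(davg), each = HW) / HW, d)
  dxm <- matrix(0, HW, C * B)
  dxm[cbind(cc$pool$argmax, seq_len(C * B))] <- as.vector(dmx)
  dx + array(dxm, d)
}

cbam_mlp_bwd <- function(ly, dz, fw, P) {
  ly$grad$W2 <- ly$grad$W2 + dz %*% t(fw$hidden)
  dH <- (t(ly$par$W2) %*% dz) * (fw$hidden > 0)
  ly$grad$W1 <- ly$grad$W1 + dH %*% t(P)
  t(ly$par$W1) %*% dH
}
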