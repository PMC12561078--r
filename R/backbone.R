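# 18-layer residual image backbone with CBAM between the two basic blocks of
# every stage:
#   O0 = BasicBlock0(F_{i-1});  O0' = CBAM(O0);  F_i = BasicBlock1(O0 + O0')
#
# Full schedule (224 px input): 7x7/2 stem + 3x3/2 maxpool, stage widths
# 64/128/256/512, spatial halving at stages 2-4 (stage-3 grid 14x14x256).
# Tiny schedule (32 px input, desk-scale tests): 3x3/1 stem, widths /4.

basic_block <- function(cin, cout, stride = 1L) {
  bk <- list(conv1 = conv_layer(3, 3, cin, cout, stride = stride, pad = 1),
             bn1 = bn_layer(cout),
             relu1 = relu_layer(),
             conv2 = conv_layer(3, 3, cout, cout, stride = 1, pad = 1),
             bn2 = bn_layer(cout),
             relu2 = relu_layer(),
             down_conv = NULL, down_bn = NULL)
  if (stride != 1 || cin != cout) {
    bk$down_conv <- conv_layer(1, 1, cin, cout, stride = stride, pad = 0)
    bk$down_bn <- bn_layer(cout)
  }
  bk
}

bb_fwd <- function(bk, x, training) {
  h <- conv_fwd(bk$conv1, x)
  h <- bn_fwd(bk$bn1, h, training)
  h <- relu_fwd(bk$relu1, h)
  h <- conv_fwd(bk$conv2, h)
  h <- bn_fwd(bk$bn2, h, training)
  s <- if (!is.null(bk$down_conv))
    bn_fwd(bk$down_bn, conv_fwd(bk$down_conv, x), training) else x
  relu_fwd(bk$relu2, h + s)
}

bb_bwd <- function(bk, dy) {
  dsum <- relu_bwd(bk$relu2, dy)
  dh <- bn_bwd(bk$bn2, dsum)
  dh <- conv_bwd(bk$conv2, dh)
  dh <- relu_bwd(bk$relu1, dh)
  dh <- bn_bwd(bk$bn1, dh)
  dx <- conv_bwd(bk$conv1, dh)
  ds <- if (!is.null(bk$down_conv))
    conv_bwd(bk$down_conv, bn_bwd(bk$down_bn, dsum)) else dsum
  dx + ds
}

make_stage <- function(cin, cout, stride, use_cbam, reduction, spatial_kernel) {
  st <- list(block0 = basic_block(cin, cout, stride),
             cbam = NULL,
             block1 = basic_block(cout, cout, 1L))
  if (use_cbam)
    st$cbam <- cbam_layer(cout, reduction = reduction,
                          spatial_kernel = spatial_kernel)
  st
}

#' Run one backbone stage
#'
#' Applies basic block 0, refines its output with CBAM (when the stage has
#' one), and feeds the additive combination `O0 + O0'` to basic block 1.
#' Forcing the CBAM output to the zero map therefore reduces the stage to the
#' plain residual stage `BasicBlock1(BasicBlock0(F_prev))`.
#'
#' @param F_prev input feature map `(H, W, C, B)`.
#' @param stage a stage object from the backbone of [build_neuronet()].
#' @param training logical; batch-norm mode.
#' @return output feature map.
#' @export
stage_forward <- function(F_prev, stage, training = FALSE) {
  o0 <- bb_fwd(stage$block0, F_prev, training)
  xin <- if (!is.null(stage$cbam)) o0 + cbam_fwd(stage$cbam, o0) else o0
  bb_fwd(stage$block1, xin, training)
}

stage_backward <- function(stage, dy) {
  dxin <- bb_bwd(stage$block1, dy)
  do0 <- if (!is.null(stage$cbam)) dxin + cbam_bwd(stage$cbam, dxin) else dxin
  bb_bwd(stage$block0, do0)
}

## ---- image tokens ----------------------------------------------------------

#' Project a stage-3 feature map to image tokens
#'
#' Per channel, the flattened `H x W` spatial vector is linearly mapped to
#' length `E`, yielding `(C, E, B)` tokens: channel c of sample b becomes row
#' c of a `C x E` token matrix. Under the full schedule this is
#' `(256, 256, B)`, aligning with the text side.
#'
#' @param F3 stage-3 output `(H, W, C, B)`.
#' @param projection `(H*W) x E` projection matrix.
#' @return `(C, E, B)` array of image tokens.
#' @export
to_image_tokens <- function(F3, projection) {
  d <- dim(F3)
  HW <- d[1] * d[2]; C <- d[3]; B <- d[4]
  if (nrow(projection) != HW)
    nn_stop("backbone_error", "projection expects %d spatial positions, got %d",
            nrow(projection), HW)
  E <- ncol(projection)
  out <- array(0, c(C, E, B))
  for (b in seq_len(B)) {
    Fb <- matrix(F3[, , , b], nrow = HW)    # HW x C
    out[, , b] <- crossprod(Fb, projection) # C x E
  }
  out
}

## ---- schedules -------------------------------------------------------------

backbone_widths <- function(config) {
  config$widths %||% if (config$tiny) c(16L, 32L, 64L, 128L)
                     else c(64L, 128L, 256L, 512L)
}

# spatial side of each stage output for a square input
backbone_grid <- function(config) {
  s <- config$image_size
  if (config$tiny) {
    s1 <- s                     # 3x3/1 stem
  } else {
    s1 <- ceiling(ceiling(s / 2) / 2)  # 7x7/2 stem then 3x3/2 maxpool
  }
  c(s1, ceiling(s1 / 2), ceiling(s1 / 4), ceiling(s1 / 8))
}

build_backbone <- function(config) {
  w <- backbone_widths(config)
  red <- config$cbam_reduction
  spk <- config$spatial_kernel
  stem_cin <- 3L
  if (config$tiny) {
    stem <- list(conv = conv_layer(3, 3, stem_cin, w[1], stride = 1, pad = 1),
                 bn = bn_layer(w[1]), relu = relu_layer(), pool = NULL)
  } else {
    stem <- list(conv = conv_layer(7, 7, stem_cin, w[1], stride = 2, pad = 3),
                 bn = bn_layer(w[1]), relu = relu_layer(),
                 pool = maxpool_layer(3, 2, 1))
  }
  stages <- list(
    make_stage(w[1], w[1], 1L, config$use_cbam, red, spk),
    make_stage(w[1], w[2], 2L, config$use_cbam, red, spk),
    make_stage(w[2], w[3], 2L, config$use_cbam, red, spk),
    make_stage(w[3], w[4], 2L, config$use_cbam, red, spk))
  list(stem = stem, stages = stages)
}

stem_fwd <- function(bb, x, training) {
  h <- conv_fwd(bb$stem$conv, x)
  h <- bn_fwd(bb$stem$bn, h, training)
  h <- relu_fwd(bb$stem$relu, h)
  if (!is.null(bb$stem$pool)) h <- maxpool_fwd(bb$stem$pool, h)
  h
}

stem_bwd <- function(bb, dy) {
  if (!is.null(bb$stem$pool)) dy <- maxpool_bwd(bb$stem$pool, dy)
  dy <- relu_bwd(bb$stem$relu, dy)
  dy <- bn_bwd(bb$stem$bn, dy)
  conv_bwd(bb$stem$conv, dy)
}
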