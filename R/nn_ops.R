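# Low-level differentiable layers.
#
# Feature maps are numeric arrays with dim (H, W, C, B); fully connected
# activations are (B x n) matrices. Every layer is an environment holding
# $par (named list of arrays), $grad (same shapes, accumulated by *_bwd),
# $buf (non-trainable state such as batch-norm running moments) and $cache
# (whatever the matching backward pass needs). Backward functions return the
# gradient with respect to the layer input.

new_layer <- function(type, par = list(), buf = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$par <- par
  e$buf <- buf
  e$grad <- NULL
  e$cache <- NULL
  e$opt <- NULL
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

zero_grad <- function(ly) {
  ly$grad <- lapply(ly$par, function(p) p * 0)
  invisible(ly)
}

## ---- convolution (Rcpp kernels) -------------------------------------------

conv_layer <- function(kh, kw, cin, cout, stride = 1L, pad = 0L) {
  fan_in <- kh * kw * cin
  W <- array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / fan_in)),
             dim = c(kh, kw, cin, cout))
  new_layer("conv", par = list(W = W, b = numeric(cout)),
            buf = list(stride = as.integer(stride), pad = as.integer(pad)))
}

conv_fwd <- function(ly, x) {
  ly$cache <- x
  conv2d_fwd_cpp(x, ly$par$W, ly$par$b, ly$buf$stride, ly$buf$pad)
}

conv_bwd <- function(ly, dy) {
  r <- conv2d_bwd_cpp(ly$cache, ly$par$W, dy, ly$buf$stride, ly$buf$pad)
  ly$grad$W <- ly$grad$W + r$dw
  ly$grad$b <- ly$grad$b + r$db
  r$dx
}

## ---- batch normalization ---------------------------------------------------

# Per-channel normalization over (H, W, B); batch moments in training mode,
# exponentially-averaged running moments (momentum 0.1) in eval mode.

bn_layer <- function(C, eps = 1e-5, momentum = 0.1) {
  new_layer("bn",
            par = list(gamma = rep(1, C), beta = rep(0, C)),
            buf = list(running_mean = rep(0, C), running_var = rep(1, C),
                       eps = eps, momentum = momentum, C = C))
}

bn_fwd <- function(ly, x, training) {
  r <- bn_fwd_cpp(x, ly$par$gamma, ly$par$beta, ly$buf$running_mean,
                  ly$buf$running_var, ly$buf$eps, training)
  if (training) {
    n <- dim(x)[1] * dim(x)[2] * dim(x)[4]
    mom <- ly$buf$momentum
    ly$buf$running_mean <- (1 - mom) * ly$buf$running_mean + mom * r$mean
    # the unbiased estimate feeds the running variance, as is conventional
    ly$buf$running_var <- (1 - mom) * ly$buf$running_var +
      mom * r$var * n / max(n - 1, 1)
  }
  ly$cache <- list(x = x, mean = r$mean, invstd = r$invstd,
                   training = training)
  r$y
}

bn_bwd <- function(ly, dy) {
  cc <- ly$cache
  r <- bn_bwd_cpp(cc$x, dy, ly$par$gamma, cc$mean, cc$invstd, cc$training)
  ly$grad$gamma <- ly$grad$gamma + r$dgamma
  ly$grad$beta <- ly$grad$beta + r$dbeta
  r$dx
}

## ---- relu / dropout / linear ----------------------------------------------

relu_layer <- function() new_layer("relu")

maxpool_layer <- function(k, stride, pad) {
  new_layer("maxpool", buf = list(k = as.integer(k), stride = as.integer(stride),
                                  pad = as.integer(pad)))
}

maxpool_fwd <- function(ly, x) {
  r <- maxpool_fwd_cpp(x, ly$buf$k, ly$buf$stride, ly$buf$pad)
  ly$cache <- list(argmax = r$argmax, xdim = dim(x))
  r$y
}

maxpool_bwd <- function(ly, dy) {
  maxpool_bwd_cpp(dy, ly$cache$argmax, ly$cache$xdim)
}

relu_fwd <- function(ly, x) {
  ly$cache <- x
  relu_fwd_cpp(x)
}

relu_bwd <- function(ly, dy) relu_bwd_cpp(ly$cache, dy)

dropout_layer <- function(rate) new_layer("dropout", buf = list(rate = rate))

dropout_fwd <- function(ly, x, training) {
  rate <- ly$buf$rate
  if (!training || rate <= 0) {
    ly$cache <- NULL
    return(x)
  }
  keep <- 1 - rate
  mask <- (matrix(runif(length(x)), nrow = nrow(x)) < keep) / keep
  ly$cache <- mask
  x * mask
}

dropout_bwd <- function(ly, dy) {
  if (is.null(ly$cache)) dy else dy * ly$cache
}

linear_layer <- function(n_in, n_out, sd = NULL) {
  sd <- sd %||% sqrt(1 / n_in)
  new_layer("linear",
            par = list(W = matrix(rnorm(n_in * n_out, sd = sd), n_in, n_out),
                       b = numeric(n_out)))
}

linear_fwd <- function(ly, x) {
  ly$cache <- x
  sweep(x %*% ly$par$W, 2, ly$par$b, `+`)
}

linear_bwd <- function(ly, dy) {
  ly$grad$W <- ly$grad$W + crossprod(ly$cache, dy)
  ly$grad$b <- ly$grad$b + colSums(dy)
  dy %*% t(ly$par$W)
}

## ---- softmax ---------------------------------------------------------------

#' Row-wise softmax
#'
#' @param z numeric matrix of logits (rows are samples).
#' @return matrix of the same shape; every row is non-negative and sums to 1.
#' @export
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Backward of row softmax given upstream dP: dZ = P * (dP - rowSums(dP * P))
softmax_rows_bwd <- function(P, dP) {
  P * (dP - rowSums(dP * P))
}
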