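# Full network assembly: stem -> stages 1-3 -> MGCA fusion -> stage 4 ->
# flatten -> dropout -> fully connected -> softmax.

#' Network configuration
#'
#' Component toggles mirror the ablation axes: CBAM in the backbone, MGCA
#' fusion, metadata use, feature selection, and the text encoder (serialized
#' text vs. bare numeric value tokens). The text encoder requires metadata;
#' MGCA requires metadata.
#'
#' @param n_classes 2 (NC vs AD) or 3 (NC, MCI, AD); class order is fixed as
#'   NC = 1, MCI = 2, AD = 3 (MCI dropped in binary mode).
#' @param tiny use the desk-scale schedule (32 px input, widths / 4).
#' @param image_size square input side; defaults 224 (full) / 32 (tiny).
#' @param use_cbam,use_mgca,use_metadata,use_feature_selection,use_text_encoder
#'   component toggles.
#' @param n_heads MGCA heads (1, 2, 4 or 8; default 4).
#' @param embed_dim shared embedding dimension `E`; defaults 256 (full) /
#'   64 (tiny).
#' @param text_max_len text sequence length `L`; defaults 256 (full) /
#'   32 (tiny).
#' @param text_hidden stand-in encoder hidden size `H`; defaults 64 / 32.
#' @param cbam_reduction channel-attention bottleneck ratio; defaults 16 / 4.
#' @param spatial_kernel CBAM spatial kernel side (default 7).
#' @param attn_scale `"sqrt"` or `"linear"` attention scaling.
#' @param dropout dropout rate on the fully connected head (default 0.5).
#' @param widths optional 4-vector overriding the stage widths (micro tests).
#' @param pretrained optional path to a saved parameter file to load into the
#'   backbone (no weights ship with the package; random init is the default).
#' @return a `neuronet_config` list.
#' @export
neuronet_config <- function(n_classes = 3,
                            tiny = FALSE,
                            image_size = if (tiny) 32 else 224,
                            use_cbam = TRUE,
                            use_mgca = TRUE,
                            use_metadata = TRUE,
                            use_feature_selection = TRUE,
                            use_text_encoder = TRUE,
                            n_heads = 4,
                            embed_dim = if (tiny) 64 else 256,
                            text_max_len = if (tiny) 32 else 256,
                            text_hidden = if (tiny) 32 else 64,
                            cbam_reduction = if (tiny) 4 else 16,
                            spatial_kernel = 7,
                            attn_scale = "sqrt",
                            dropout = 0.5,
                            widths = NULL,
                            pretrained = NULL) {
  if (!n_classes %in% c(2, 3))
    nn_stop("config_error", "n_classes must be 2 or 3")
  if (use_text_encoder && !use_metadata)
    nn_stop("config_error", "use_text_encoder requires use_metadata")
  if (use_mgca && !use_metadata)
    nn_stop("config_error", "use_mgca requires use_metadata")
  if (!use_mgca && use_metadata && use_text_encoder)
    nn_stop("config_error", "metadata can only enter through MGCA fusion")
  cfg <- list(n_classes = as.integer(n_classes),
              classes = if (n_classes == 3) AD_CLASSES else c("NC", "AD"),
              tiny = tiny, image_size = as.integer(image_size),
              use_cbam = use_cbam, use_mgca = use_mgca,
              use_metadata = use_metadata,
              use_feature_selection = use_feature_selection,
              use_text_encoder = use_text_encoder,
              n_heads = as.integer(n_heads),
              embed_dim = as.integer(embed_dim),
              text_max_len = as.integer(text_max_len),
              text_hidden = as.integer(text_hidden),
              cbam_reduction = as.integer(cbam_reduction),
              spatial_kernel = as.integer(spatial_kernel),
              attn_scale = attn_scale, dropout = dropout,
              widths = if (!is.null(widths)) as.integer(widths) else NULL,
              pretrained = pretrained)
  class(cfg) <- "neuronet_config"
  cfg
}

#' Build a network from a configuration
#'
#' @param config a [neuronet_config()].
#' @param seed integer seed for weight initialization.
#' @return a `neuronet_model` environment holding the layer tree.
#' @export
build_neuronet <- function(config, seed = 1) {
  stopifnot(inherits(config, "neuronet_config"))
  set.seed(seed)
  model <- new.env(parent = emptyenv())
  model$config <- config
  model$seed <- as.integer(seed)
  model$backbone <- build_backbone(config)
  grid <- backbone_grid(config)
  w <- backbone_widths(config)
  hw3 <- grid[3]^2
  if (config$use_mgca) {
    model$mgca <- mgca_layer(config$embed_dim, config$n_heads, hw3,
                             config$attn_scale)
    model$text_proj <- linear_layer(config$text_hidden, config$embed_dim)
  }
  n_flat <- grid[4]^2 * w[4]
  model$dropout <- dropout_layer(config$dropout)
  model$fc <- linear_layer(n_flat, config$n_classes)
  model$grid <- grid
  if (!is.null(config$pretrained))
    set_model_params(model, readRDS(config$pretrained))
  class(model) <- "neuronet_model"
  model
}

# All layer environments of a model, in a stable order.
model_layers <- function(model) {
  out <- list(model$backbone$stem$conv, model$backbone$stem$bn)
  for (st in model$backbone$stages) {
    for (bk in list(st$block0, st$block1)) {
      out <- c(out, list(bk$conv1, bk$bn1, bk$conv2, bk$bn2))
      if (!is.null(bk$down_conv)) out <- c(out, list(bk$down_conv, bk$down_bn))
    }
    if (!is.null(st$cbam)) out <- c(out, list(st$cbam))
  }
  if (!is.null(model$mgca)) out <- c(out, list(model$mgca, model$text_proj))
  c(out, list(model$fc))
}

#' Number of trainable parameters
#'
#' @param model a `neuronet_model`.
#' @return integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model_layers(model),
             function(ly) sum(vapply(ly$par, length, 0L)), 0L))
}

get_model_params <- function(model) {
  lapply(model_layers(model), function(ly)
    list(par = lapply(ly$par, function(p) p + 0),
         buf = list(running_mean = ly$buf$running_mean,
                    running_var = ly$buf$running_var)))
}

set_model_params <- function(model, snapshot) {
  lys <- model_layers(model)
  stopifnot(length(lys) == length(snapshot))
  for (i in seq_along(lys)) {
    lys[[i]]$par <- snapshot[[i]]$par
    if (!is.null(snapshot[[i]]$buf$running_mean)) {
      lys[[i]]$buf$running_mean <- snapshot[[i]]$buf$running_mean
      lys[[i]]$buf$running_var <- snapshot[[i]]$buf$running_var
    }
  }
  invisible(model)
}

## ---- forward / loss / backward --------------------------------------------

# images: (H, W, B) or (H, W, 1|3, B); grayscale is replicated to 3 channels.
prep_images <- function(images) {
  d <- dim(images)
  if (length(d) == 3) {
    images <- array(images, c(d[1], d[2], 1, d[3]))
    d <- dim(images)
  }
  if (d[3] == 1) {
    x <- array(0, c(d[1], d[2], 3, d[4]))
    for (c in 1:3) x[, , c, ] <- images[, , 1, ]
    x
  } else images
}

#' Forward pass
#'
#' @param model a `neuronet_model`.
#' @param images `(H, W, B)` or `(H, W, C, B)` array in `[0, 1]`.
#' @param text_embeddings `(L, H, B)` array from [encode_text()], or `NULL`
#'   for image-only configurations.
#' @param training logical: batch-norm batch statistics + dropout.
#' @return list with `prob` (`B x n_classes`, rows sum to 1), `logits`, and
#'   `flat` (the flattened stage-4 features).
#' @export
neuronet_forward <- function(model, images, text_embeddings = NULL,
                             training = FALSE) {
  cfg <- model$config
  x <- prep_images(images)
  if (dim(x)[1] != cfg$image_size)
    nn_stop("model_error", "model expects %d px input, got %d",
            cfg$image_size, dim(x)[1])
  B <- dim(x)[4]
  h <- stem_fwd(model$backbone, x, training)
  h <- stage_forward(h, model$backbone$stages[[1]], training)
  h <- stage_forward(h, model$backbone$stages[[2]], training)
  h <- stage_forward(h, model$backbone$stages[[3]], training)
  if (cfg$use_mgca) {
    if (is.null(text_embeddings))
      nn_stop("model_error", "fusion configuration needs text embeddings")
    if (dim(text_embeddings)[3] != B)
      nn_stop("model_error", "batch misalignment: %d images vs %d texts",
              B, dim(text_embeddings)[3])
    model$text_cache <- text_embeddings
    Tp <- text_proj_fwd(model$text_proj, text_embeddings)
    h <- mgca_fwd(model$mgca, h, Tp)
  }
  h <- stage_forward(h, model$backbone$stages[[4]], training)
  model$f4_dim <- dim(h)
  flat <- t(matrix(h, ncol = B))                       # B x n_flat
  dp <- dropout_fwd(model$dropout, flat, training)
  logits <- linear_fwd(model$fc, dp)
  list(prob = softmax_rows(logits), logits = logits, flat = flat)
}

# Linear projection of text embeddings (L,H,B) -> (L,E,B) with cached input.
text_proj_fwd <- function(ly, T) {
  d <- dim(T)
  E <- ncol(ly$par$W)
  out <- array(0, c(d[1], E, d[3]))
  for (b in seq_len(d[3]))
    out[, , b] <- sweep(matrix(T[, , b], d[1], d[2]) %*% ly$par$W, 2,
                        ly$par$b, `+`)
  ly$cache <- T
  out
}

text_proj_bwd <- function(ly, dTp) {
  T <- ly$cache
  d <- dim(T)
  for (b in seq_len(d[3])) {
    Tb <- matrix(T[, , b], d[1], d[2])
    db <- matrix(dTp[, , b], d[1], ncol(ly$par$W))
    ly$grad$W <- ly$grad$W + crossprod(Tb, db)
    ly$grad$b <- ly$grad$b + colSums(db)
  }
  invisible(NULL)
}

#' Categorical cross-entropy
#'
#' Mean over the batch of `-sum_j y_j log(yhat_j)` with probabilities clamped
#' at `1e-12` before the log.
#'
#' @param prob `B x K` matrix of predicted probabilities.
#' @param onehot `B x K` one-hot label matrix.
#' @return non-negative scalar.
#' @export
cross_entropy <- function(prob, onehot) {
  prob <- as.matrix(prob); onehot <- as.matrix(onehot)
  if (!all(onehot %in% c(0, 1)) || !all(rowSums(onehot) == 1))
    nn_stop("loss_error", "labels must be one-hot rows")
  p <- pmin(pmax(prob, 1e-12), 1)
  mean(-rowSums(onehot * log(p)))
}

onehot_labels <- function(labels, classes) {
  y <- matrix(0, length(labels), length(classes))
  y[cbind(seq_along(labels), match(as.character(labels), classes))] <- 1
  y
}

# Backward from dlogits (B x K). Call immediately after a training forward.
neuronet_backward <- function(model, dlogits) {
  cfg <- model$config
  dflat <- dropout_bwd(model$dropout, linear_bwd(model$fc, dlogits))
  B <- nrow(dflat)
  dh <- array(t(dflat), model$f4_dim)
  dh <- stage_backward(model$backbone$stages[[4]], dh)
  if (cfg$use_mgca) {
    r <- mgca_bwd(model$mgca, dh)
    dh <- r$dx
    text_proj_bwd(model$text_proj, r$dTp)
  }
  dh <- stage_backward(model$backbone$stages[[3]], dh)
  dh <- stage_backward(model$backbone$stages[[2]], dh)
  dh <- stage_backward(model$backbone$stages[[1]], dh)
  stem_bwd(model$backbone, dh)
}

zero_model_grads <- function(model) {
  for (ly in model_layers(model)) zero_grad(ly)
  invisible(model)
}

## ---- Adam ------------------------------------------------------------------

adam_state <- function(model) {
  model$adam_t <- 0L
  for (ly in model_layers(model))
    ly$opt <- lapply(ly$par, function(p) list(m = p * 0, v = p * 0))
  invisible(model)
}

adam_step <- function(model, lr = 1e-3, weight_decay = 1e-5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  model$adam_t <- model$adam_t + 1L
  t <- model$adam_t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (ly in model_layers(model)) {
    for (nm in names(ly$par)) {
      g <- ly$grad[[nm]] + weight_decay * ly$par[[nm]]
      st <- ly$opt[[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      ly$opt[[nm]] <- st
      ly$par[[nm]] <- ly$par[[nm]] - lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  invisible(model)
}
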