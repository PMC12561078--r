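# Cross-validation harness, held-out evaluation, ablation runner, FLOPs
# estimate and gradient-weighted class activation maps.

#' Subject-level 5-fold cross-validation
#'
#' Trains one model per fold on the other folds, evaluates on the held fold
#' (slice level and subject level), and aggregates mean, n-1 sd and a
#' t-based 95% confidence interval (df = n_folds - 1). Held-out subjects are
#' never touched; the no-leakage assertion runs before every fit.
#'
#' @param cohort list of subject records.
#' @param plan a `split_plan` from [assign_splits()].
#' @param config a [neuronet_config()].
#' @param train_cfg a [training_config()].
#' @param metric_level `"slice"` or `"subject"` accuracy granularity for the
#'   fold summaries (both are recorded).
#' @param ... passed on to [train_neuronet()] (e.g. a precomputed
#'   `feature_ranking`).
#' @return `cv_summary`: list with `fold_reports` (per-fold
#'   `metrics_report`), `fold_accuracy`, `summary` (mean/sd/CI), `history`
#'   of each fold's fit.
#' @export
run_cross_validation <- function(cohort, plan, config,
                                 train_cfg = training_config(),
                                 metric_level = c("subject", "slice"),
                                 ...) {
  metric_level <- match.arg(metric_level)
  n_folds <- length(plan$folds)
  assert_no_leakage(plan)
  reports <- vector("list", n_folds)
  acc <- numeric(n_folds)
  hist <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    mem <- fold_members(plan, f)
    stopifnot(length(intersect(mem$train, plan$held_out)) == 0,
              length(intersect(mem$validation, plan$held_out)) == 0)
    fit <- train_neuronet(cohort, mem$train, mem$validation, config,
                          train_cfg = train_cfg, ...)
    pr <- predict_neuronet(fit, cohort, mem$validation)
    if (metric_level == "subject") {
      rep <- compute_metrics(pr$subject$predicted, pr$subject$label,
                             fit$classes)
    } else {
      rep <- compute_metrics(pr$slice$predicted, pr$slice$label, fit$classes,
                             prob = as.matrix(pr$slice[, fit$classes]))
    }
    reports[[f]] <- rep
    acc[f] <- rep$overall$accuracy
    hist[[f]] <- fit$history
  }
  structure(list(fold_reports = reports, fold_accuracy = acc,
                 summary = fold_summary(acc), history = hist,
                 metric_level = metric_level),
            class = "cv_summary")
}

#' Train on the full CV pool and evaluate on the held-out subjects
#'
#' @param cohort list of subject records.
#' @param plan a `split_plan`.
#' @param config a [neuronet_config()].
#' @param train_cfg a [training_config()]; one CV fold is reused as the
#'   early-stopping validation set.
#' @return list with `fit`, `slice_report` and `subject_report`.
#' @export
evaluate_heldout <- function(cohort, plan, config,
                             train_cfg = training_config()) {
  mem <- fold_members(plan, length(plan$folds))
  fit <- train_neuronet(cohort, mem$train, mem$validation, config, train_cfg)
  pr <- predict_neuronet(fit, cohort, plan$held_out)
  list(fit = fit,
       slice_report = compute_metrics(pr$slice$predicted, pr$slice$label,
                                      fit$classes,
                                      prob = as.matrix(pr$slice[, fit$classes])),
       subject_report = compute_metrics(pr$subject$predicted,
                                        pr$subject$label, fit$classes))
}

## ---- ablation --------------------------------------------------------------

# Component grids: additive build-up, leave-one-out, and the head-count grid.
ablation_grid <- function(base_config, which = c("additive", "leave_one_out",
                                                 "heads")) {
  which <- match.arg(which)
  mod <- function(...) {
    args <- list(...)
    cfg <- unclass(base_config)
    cfg[names(args)] <- args
    do.call(neuronet_config,
            cfg[intersect(names(cfg), names(formals(neuronet_config)))])
  }
  switch(which,
    additive = list(
      base = mod(use_cbam = FALSE, use_mgca = FALSE, use_metadata = FALSE,
                 use_feature_selection = FALSE, use_text_encoder = FALSE),
      cbam = mod(use_mgca = FALSE, use_metadata = FALSE,
                 use_feature_selection = FALSE, use_text_encoder = FALSE),
      cbam_mgca_meta = mod(use_feature_selection = FALSE,
                           use_text_encoder = FALSE),
      plus_fs = mod(use_text_encoder = FALSE),
      full = mod()),
    leave_one_out = list(
      full = mod(),
      no_cbam = mod(use_cbam = FALSE),
      no_mgca = mod(use_mgca = FALSE, use_metadata = FALSE,
                    use_feature_selection = FALSE, use_text_encoder = FALSE),
      no_fs = mod(use_feature_selection = FALSE),
      no_te = mod(use_text_encoder = FALSE),
      no_fusion = mod(use_cbam = FALSE, use_mgca = FALSE,
                      use_metadata = FALSE, use_feature_selection = FALSE,
                      use_text_encoder = FALSE)),
    heads = {
      g <- lapply(c(1L, 2L, 4L, 8L), function(h) mod(n_heads = h))
      names(g) <- paste0("heads_", c(1, 2, 4, 8))
      g
    })
}

#' Run a component / head-count ablation
#'
#' Every cell trains on byte-identical partitions (one fold of the plan
#' validates, the rest train) with a shared seed, then evaluates on the held
#' fold. Reports accuracy/precision/recall/F1 plus parameter count and an
#' analytic FLOPs estimate per cell. FLOPs absolute values depend on the
#' counting convention and input resolution and are reported, not asserted.
#'
#' @param cohort list of subject records.
#' @param plan a `split_plan`.
#' @param base_config the full-model [neuronet_config()] the grid modifies.
#' @param train_cfg a [training_config()] shared by all cells.
#' @param which `"additive"`, `"leave_one_out"` or `"heads"`.
#' @param fold which fold validates (default 1).
#' @param ... passed on to [train_neuronet()].
#' @return data.frame: one row per cell with metrics, `n_parameters`,
#'   `flops_g`.
#' @export
run_ablation <- function(cohort, plan, base_config,
                         train_cfg = training_config(),
                         which = c("additive", "leave_one_out", "heads"),
                         fold = 1, ...) {
  which <- match.arg(which)
  grid <- ablation_grid(base_config, which)
  mem <- fold_members(plan, fold)
  rows <- lapply(names(grid), function(nm) {
    cfg <- grid[[nm]]
    fit <- train_neuronet(cohort, mem$train, mem$validation, cfg, train_cfg,
                          ...)
    pr <- predict_neuronet(fit, cohort, mem$validation)
    rep <- compute_metrics(pr$subject$predicted, pr$subject$label, fit$classes)
    data.frame(variant = nm,
               accuracy = rep$overall$accuracy,
               precision = rep$overall$precision,
               recall = rep$overall$recall,
               f1 = rep$overall$f1,
               n_parameters = n_parameters(fit$model),
               flops_g = flops_estimate(cfg) / 1e9,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Analytic FLOPs estimate
#'
#' Counts one multiply-accumulate as 2 FLOPs over all convolutions, linear
#' layers, attention projections and softmax evaluations at the configured
#' input resolution. Head-count enters through the per-head softmax work, so
#' the estimate strictly increases with `n_heads`.
#'
#' @param config a [neuronet_config()].
#' @return FLOPs per single input (scalar).
#' @export
flops_estimate <- function(config) {
  g <- backbone_grid(config)
  w <- backbone_widths(config)
  s_in <- config$image_size
  fl <- 0
  conv_fl <- function(side, cin, cout, k) 2 * side^2 * cin * cout * k^2
  if (config$tiny) {
    fl <- fl + conv_fl(s_in, 3, w[1], 3)
  } else {
    fl <- fl + conv_fl(ceiling(s_in / 2), 3, w[1], 7)
  }
  cins <- c(w[1], w[1:3])
  for (i in 1:4) {
    side <- g[i]
    # block0 (possibly strided with 1x1 downsample) + block1
    fl <- fl + conv_fl(side, cins[i], w[i], 3) + 3 * conv_fl(side, w[i], w[i], 3)
    if (cins[i] != w[i]) fl <- fl + conv_fl(side, cins[i], w[i], 1)
    if (config$use_cbam) {
      cr <- w[i] %/% config$cbam_reduction
      fl <- fl + 2 * (2 * w[i] * cr) * 2          # shared MLP, two branches
      fl <- fl + conv_fl(side, 2, 1, config$spatial_kernel)
    }
  }
  if (config$use_mgca) {
    E <- config$embed_dim
    L <- config$text_max_len
    C <- w[3]
    hw <- g[3]^2
    d <- E / config$n_heads
    n <- config$n_heads
    fl <- fl + 2 * 2 * C * hw * E                    # token projection + inverse
    fl <- fl + 2 * L * config$text_hidden * E        # text projection
    fl <- fl + n * 2 * (C + 2 * L) * E * d           # per-head Q/K/V
    fl <- fl + n * 2 * 2 * C * L * d                 # scores + weighted sum
    fl <- fl + n * 3 * C * L                         # softmax exp/sum/div
    fl <- fl + 2 * C * E * E                         # output projection
  }
  fl + 2 * g[4]^2 * w[4] * config$n_classes          # classifier
}

## ---- class activation maps -------------------------------------------------

#' Gradient-weighted class activation map
#'
#' Backpropagates the target-class logit to the last convolution of stage 4,
#' weights that activation by the spatial mean of its gradient, rectifies,
#' min-max normalizes to `[0, 1]` and upsamples to the input size.
#'
#' @param fit a `neuronet_fit` (or a `neuronet_model`).
#' @param image one slice matrix.
#' @param target_class class name or index.
#' @param metadata optional named metadata list for fusion configurations;
#'   if omitted, the subject-independent zero text embedding is used.
#' @param text_embedding optional precomputed `(L, H)` embedding matrix.
#' @return `image_size x image_size` heatmap in `[0, 1]`.
#' @export
class_activation_map <- function(fit, image, target_class, metadata = NULL,
                                 text_embedding = NULL) {
  model <- if (inherits(fit, "neuronet_fit")) fit$model else fit
  cfg <- model$config
  k <- if (is.character(target_class))
    match(target_class, cfg$classes) else as.integer(target_class)
  if (is.na(k) || k < 1 || k > cfg$n_classes)
    nn_stop("evaluation_error", "invalid target class")
  imgs <- array(image, c(nrow(image), ncol(image), 1))
  txt <- NULL
  if (cfg$use_mgca) {
    if (!is.null(text_embedding)) {
      txt <- array(text_embedding, c(nrow(text_embedding),
                                     ncol(text_embedding), 1))
    } else if (!is.null(metadata) && inherits(fit, "neuronet_fit")) {
      Z <- apply_standardizer(matrix(as.numeric(as.list(metadata)[fit$selected]),
                                     1, dimnames = list(NULL, fit$selected)),
                              fit$scaler)
      rec <- as.list(round(Z[1, ], 1))
      enc <- fit$encoder %||% hash_text_encoder(cfg$text_max_len, cfg$text_hidden)
      txt <- encode_text(serialize_metadata(rec, fit$selected), enc)
    } else {
      txt <- array(0, c(cfg$text_max_len, cfg$text_hidden, 1))
    }
  }
  fw <- neuronet_forward(model, imgs, txt, training = FALSE)
  # capture the activation and gradient at stage-4 block1 conv2
  last_conv <- model$backbone$stages[[4]]$block1$conv2
  act <- conv2d_fwd_cpp(last_conv$cache, last_conv$par$W, last_conv$par$b,
                        last_conv$buf$stride, last_conv$buf$pad)
  dlogits <- matrix(0, 1, cfg$n_classes)
  dlogits[1, k] <- 1
  zero_model_grads(model)
  grad <- cam_backward_to_conv2(model, dlogits)
  d <- dim(act)
  A <- array(act[, , , 1], d[1:3])
  G <- array(grad[, , , 1], d[1:3])
  wts <- apply(G, 3, mean)
  heat <- matrix(0, d[1], d[2])
  for (c in seq_len(d[3])) heat <- heat + wts[c] * A[, , c]
  heat <- pmax(heat, 0)
  rng <- range(heat)
  heat <- if (diff(rng) > 0) (heat - rng[1]) / diff(rng) else heat * 0
  resize_bilinear_unit(heat, nrow(image))
}

# backward from the logits down to stage-4 block1 conv2 *output*
cam_backward_to_conv2 <- function(model, dlogits) {
  dflat <- dropout_bwd(model$dropout, linear_bwd(model$fc, dlogits))
  dh <- array(t(dflat), model$f4_dim)
  bk <- model$backbone$stages[[4]]$block1
  dsum <- relu_bwd(bk$relu2, dh)
  bn_bwd(bk$bn2, dsum)
}

resize_bilinear_unit <- function(m, out) {
  if (nrow(m) == out) return(m)
  r <- EBImage::resize(m, w = out, h = out)
  matrix(pmin(pmax(as.numeric(r), 0), 1), out, out)
}
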