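# Training loop: Adam (lr 0.001, weight decay 1e-5), dropout 0.5 on the
# fully connected head, training-only slice augmentation, and early stopping
# with patience on validation accuracy; the best-validation checkpoint (not
# the last) is returned. Slices are the training samples; every slice
# carries its subject's metadata and label, and splits are subject-level.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param weight_decay L2 penalty inside Adam (default 1e-5).
#' @param batch_size slices per batch (default 32).
#' @param max_epochs epoch cap (default 100).
#' @param patience early-stopping patience on validation accuracy, in epochs
#'   (default 20).
#' @param seed integer seed controlling shuffling, augmentation and dropout.
#' @param augment an [augmentation_config()]; applied to training slices
#'   only.
#' @return a `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-3, weight_decay = 1e-5,
                            batch_size = 32, max_epochs = 100, patience = 20,
                            seed = 1, augment = augmentation_config()) {
  if (patience < 1) nn_stop("config_error", "patience must be >= 1")
  if (max_epochs < 1 || batch_size < 1)
    nn_stop("config_error", "max_epochs and batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 augment = augment),
            class = "training_config")
}

#' Early-stopping arithmetic
#'
#' Given a validation-accuracy sequence, returns the epoch of the last strict
#' improvement and the epoch at which training halts: the first epoch whose
#' distance from the best epoch reaches `patience` (or the end of the
#' sequence). A sequence with its only peak at epoch 5 and patience 20 halts
#' at epoch 25 exactly.
#'
#' @param val_accuracy numeric vector, one entry per epoch.
#' @param patience consecutive non-improving epochs tolerated.
#' @return list with `best_epoch` and `stop_epoch`.
#' @export
early_stopping_epochs <- function(val_accuracy, patience) {
  best <- -Inf
  best_epoch <- 0L
  for (e in seq_along(val_accuracy)) {
    if (val_accuracy[e] > best) {
      best <- val_accuracy[e]
      best_epoch <- e
    } else if (e - best_epoch >= patience) {
      return(list(best_epoch = best_epoch, stop_epoch = e))
    }
  }
  list(best_epoch = best_epoch, stop_epoch = length(val_accuracy))
}

# Per-subject text embeddings for the configured text path.
subject_text_embeddings <- function(cohort, ids, selected, scaler, config,
                                    encoder = NULL) {
  md <- cohort_metadata(cohort)
  rownames(md) <- md$subject_id
  X <- as.matrix(md[ids, selected, drop = FALSE])
  Z <- apply_standardizer(X, scaler)
  enc <- encoder %||% hash_text_encoder(config$text_max_len, config$text_hidden)
  texts <- vapply(seq_along(ids), function(i) {
    rec <- as.list(round(Z[i, ], 1))
    names(rec) <- selected
    if (config$use_text_encoder) serialize_metadata(rec, selected)
    else paste(sprintf("%.1f", unlist(rec)), collapse = " ")
  }, "")
  T <- encode_text(texts, enc)
  out <- lapply(seq_along(ids), function(i) matrix(T[, , i], dim(T)[1], dim(T)[2]))
  names(out) <- ids
  out
}

# Stack per-subject (L,H) matrices into an (L,H,B) array for a slice batch.
stack_text <- function(emb_by_subject, subject_ids) {
  L <- nrow(emb_by_subject[[1]])
  H <- ncol(emb_by_subject[[1]])
  out <- array(0, c(L, H, length(subject_ids)))
  for (b in seq_along(subject_ids)) out[, , b] <- emb_by_subject[[subject_ids[b]]]
  out
}

# Stack slices (list of matrices) into (H, W, B), optionally augmenting.
stack_images <- function(cohort_by_id, subject_ids, slice_idx, augment = NULL) {
  img1 <- cohort_by_id[[subject_ids[1]]]$slices[[slice_idx[1]]]
  out <- array(0, c(nrow(img1), ncol(img1), length(subject_ids)))
  for (b in seq_along(subject_ids)) {
    img <- cohort_by_id[[subject_ids[b]]]$slices[[slice_idx[b]]]
    if (!is.null(augment)) img <- augment_slice(img, augment)
    out[, , b] <- img
  }
  out
}

#' Train a network on a subject-level split
#'
#' Asserts that the train and validation subject sets are disjoint, fits the
#' feature selector and metadata standardizer on training subjects only,
#' precomputes per-subject text embeddings, and runs the epoch loop with
#' early stopping on validation (slice-level) accuracy. The returned model
#' carries the parameters of the best-validation epoch.
#'
#' @param cohort list of subject records.
#' @param train_ids,val_ids disjoint subject-id vectors.
#' @param config a [neuronet_config()].
#' @param train_cfg a [training_config()].
#' @param feature_ranking optional precomputed `feature_ranking` (must have
#'   been fit without the validation subjects); by default the selector is
#'   fit on the training subjects.
#' @param encoder optional text-encoder backend (see [encode_text()]).
#' @param val_accuracy_override optional numeric vector substituted for the
#'   measured validation accuracy at each epoch; used to exercise the
#'   early-stopping rule with a known sequence.
#' @param verbose print per-epoch progress.
#' @return a `neuronet_fit`: list with `model`, `history` (data.frame),
#'   `best_epoch`, `best_val_accuracy`, `epochs_run`, `selected`, `scaler`,
#'   `classes`, plus the configs.
#' @export
train_neuronet <- function(cohort, train_ids, val_ids, config,
                           train_cfg = training_config(),
                           feature_ranking = NULL, encoder = NULL,
                           val_accuracy_override = NULL, verbose = FALSE) {
  if (length(intersect(train_ids, val_ids)) > 0)
    nn_stop("leakage_error", "train and validation subject sets overlap")
  by_id <- setNames(cohort, vapply(cohort, `[[`, "", "subject_id"))
  if (config$n_classes == 2) {
    keep <- vapply(by_id, function(s) s$label != "MCI", TRUE)
    train_ids <- train_ids[train_ids %in% names(by_id)[keep]]
    val_ids <- val_ids[val_ids %in% names(by_id)[keep]]
  }
  if (!length(train_ids) || !length(val_ids))
    nn_stop("training_error", "empty train or validation partition")
  classes <- config$classes

  selected <- METADATA_FIELDS
  scaler <- NULL
  emb <- NULL
  if (config$use_metadata) {
    if (config$use_feature_selection) {
      fr <- feature_ranking %||%
        select_features(by_id[train_ids], k = 5, seed = train_cfg$seed)
      selected <- fr$selected
    }
    md <- cohort_metadata(by_id[train_ids])
    scaler <- fit_standardizer(as.matrix(md[, selected, drop = FALSE]))
    emb <- subject_text_embeddings(cohort, c(train_ids, val_ids), selected,
                                   scaler, config, encoder)
  }

  set.seed(train_cfg$seed)
  model <- build_neuronet(config, seed = train_cfg$seed)
  adam_state(model)

  train_samples <- expand_slices(by_id, train_ids)
  val_samples <- expand_slices(by_id, val_ids)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_accuracy = numeric(), val_loss = numeric(),
                        val_accuracy = numeric())
  best_acc <- -Inf
  best_epoch <- 0L
  best_snapshot <- NULL
  n_train <- nrow(train_samples)

  for (epoch in seq_len(train_cfg$max_epochs)) {
    ord <- sample.int(n_train)
    ep_loss <- 0; ep_hits <- 0
    for (start in seq(1, n_train, by = train_cfg$batch_size)) {
      idx <- ord[start:min(start + train_cfg$batch_size - 1, n_train)]
      sb <- train_samples[idx, , drop = FALSE]
      imgs <- stack_images(by_id, sb$subject_id, sb$slice,
                           augment = if (train_cfg$augment$enabled)
                             train_cfg$augment else NULL)
      txt <- if (config$use_mgca) stack_text(emb, sb$subject_id) else NULL
      fw <- neuronet_forward(model, imgs, txt, training = TRUE)
      y <- onehot_labels(sb$label, classes)
      ep_loss <- ep_loss + cross_entropy(fw$prob, y) * length(idx)
      ep_hits <- ep_hits + sum(max.col(fw$prob) == max.col(y))
      zero_model_grads(model)
      neuronet_backward(model, (fw$prob - y) / length(idx))
      adam_step(model, lr = train_cfg$learning_rate,
                weight_decay = train_cfg$weight_decay)
    }
    ev <- evaluate_samples(model, by_id, val_samples, emb, classes)
    val_acc <- if (!is.null(val_accuracy_override))
      val_accuracy_override[epoch] else ev$accuracy
    history[epoch, ] <- list(epoch, ep_loss / n_train, ep_hits / n_train,
                             ev$loss, val_acc)
    if (verbose)
      message(sprintf("epoch %3d  train loss %.4f acc %.3f | val acc %.3f",
                      epoch, ep_loss / n_train, ep_hits / n_train, val_acc))
    if (val_acc > best_acc) {
      best_acc <- val_acc
      best_epoch <- epoch
      best_snapshot <- get_model_params(model)
    } else if (epoch - best_epoch >= train_cfg$patience) {
      break
    }
  }
  if (!is.null(best_snapshot)) set_model_params(model, best_snapshot)
  structure(list(model = model, history = history, best_epoch = best_epoch,
                 best_val_accuracy = best_acc, epochs_run = nrow(history),
                 selected = selected, scaler = scaler, classes = classes,
                 config = config, train_cfg = train_cfg,
                 encoder = encoder, emb_cache = emb),
            class = "neuronet_fit")
}

expand_slices <- function(by_id, ids) {
  do.call(rbind, lapply(ids, function(id) {
    s <- by_id[[id]]
    data.frame(subject_id = id, slice = seq_along(s$slices),
               label = s$label, stringsAsFactors = FALSE)
  }))
}

# Eval-mode loss/accuracy over a sample table, in batches.
evaluate_samples <- function(model, by_id, samples, emb, classes,
                             batch_size = 64) {
  n <- nrow(samples)
  loss <- 0; hits <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    sb <- samples[idx, , drop = FALSE]
    imgs <- stack_images(by_id, sb$subject_id, sb$slice)
    txt <- if (model$config$use_mgca) stack_text(emb, sb$subject_id) else NULL
    fw <- neuronet_forward(model, imgs, txt, training = FALSE)
    y <- onehot_labels(sb$label, classes)
    loss <- loss + cross_entropy(fw$prob, y) * length(idx)
    hits <- hits + sum(max.col(fw$prob) == max.col(y))
  }
  list(loss = loss / n, accuracy = hits / n)
}

#' Predict on subjects
#'
#' Emits per-slice probabilities and predicted labels, plus subject-level
#' predictions by majority vote over each subject's slices (ties broken by
#' the higher mean probability).
#'
#' @param fit a `neuronet_fit` from [train_neuronet()].
#' @param cohort list of subject records.
#' @param ids subject ids to predict (default: all in `cohort`).
#' @return list with `slice` (data.frame: subject_id, slice, label,
#'   predicted, one probability column per class) and `subject` (data.frame:
#'   subject_id, label, predicted).
#' @export
predict_neuronet <- function(fit, cohort, ids = NULL) {
  by_id <- setNames(cohort, vapply(cohort, `[[`, "", "subject_id"))
  ids <- ids %||% names(by_id)
  if (fit$config$n_classes == 2)
    ids <- ids[vapply(by_id[ids], function(s) s$label != "MCI", TRUE)]
  emb <- NULL
  if (fit$config$use_metadata) {
    emb <- fit$emb_cache
    missing <- setdiff(ids, names(emb %||% list()))
    if (length(missing)) {
      more <- subject_text_embeddings(cohort, missing, fit$selected,
                                      fit$scaler, fit$config, fit$encoder)
      emb <- c(emb %||% list(), more)
    }
  }
  samples <- expand_slices(by_id, ids)
  n <- nrow(samples)
  probs <- matrix(0, n, fit$config$n_classes,
                  dimnames = list(NULL, fit$classes))
  for (start in seq(1, n, by = 64)) {
    idx <- start:min(start + 63, n)
    sb <- samples[idx, , drop = FALSE]
    imgs <- stack_images(by_id, sb$subject_id, sb$slice)
    txt <- if (fit$config$use_mgca) stack_text(emb, sb$subject_id) else NULL
    fw <- neuronet_forward(fit$model, imgs, txt, training = FALSE)
    probs[idx, ] <- fw$prob
  }
  slice_df <- cbind(samples,
                    predicted = fit$classes[max.col(probs)],
                    as.data.frame(probs))
  subj <- do.call(rbind, lapply(split(seq_len(n), samples$subject_id), function(ix) {
    votes <- table(factor(slice_df$predicted[ix], levels = fit$classes))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      mp <- colMeans(probs[ix, top, drop = FALSE])
      top <- names(mp)[which.max(mp)]
    }
    data.frame(subject_id = samples$subject_id[ix[1]],
               label = samples$label[ix[1]], predicted = top,
               stringsAsFactors = FALSE)
  }))
  rownames(subj) <- NULL
  list(slice = slice_df, subject = subj)
}

#' Save a training run to a directory
#'
#' Writes `history.csv`, `manifest.json` (resolved configs, seeds, selected
#' features) and a binary `checkpoint.rds` with the best parameters.
#'
#' @param fit a `neuronet_fit`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
save_run <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(fit$history, file.path(dir, "history.csv"), row.names = FALSE)
  manifest <- list(config = unclass(fit$config),
                   train_cfg = unclass(fit$train_cfg[setdiff(names(fit$train_cfg), "augment")]),
                   augment = unclass(fit$train_cfg$augment),
                   selected = fit$selected,
                   best_epoch = fit$best_epoch,
                   best_val_accuracy = fit$best_val_accuracy,
                   epochs_run = fit$epochs_run)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  saveRDS(list(params = get_model_params(fit$model),
               scaler = fit$scaler, selected = fit$selected,
               classes = fit$classes),
          file.path(dir, "checkpoint.rds"))
  invisible(dir)
}
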