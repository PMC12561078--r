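# Network assembly, loss, gradients, and the training loop.

test_that("forward emits valid class distributions of the right shape", {
  set.seed(51)
  cfg <- micro_config()
  m <- build_neuronet(cfg, seed = 1)
  imgs <- array(runif(16 * 16 * 4), c(16, 16, 4))
  txt <- array(rnorm(8 * 5 * 4), c(8, 5, 4))
  fw <- neuronet_forward(m, imgs, txt)
  expect_equal(dim(fw$prob), c(4, 3))
  expect_equal(rowSums(fw$prob), rep(1, 4), tolerance = 1e-6)
  expect_true(all(fw$prob > 0))
  # binary configuration drops MCI and emits two columns
  cfgb <- micro_config(n_classes = 2)
  mb <- build_neuronet(cfgb, seed = 1)
  fwb <- neuronet_forward(mb, imgs, txt)
  expect_equal(dim(fwb$prob), c(4, 2))
  # misaligned batch is a model error
  expect_error(neuronet_forward(m, imgs, txt[, , 1:2]), class = "model_error")
})

test_that("configuration invariants are enforced", {
  expect_error(micro_config(use_metadata = FALSE), class = "config_error")
  expect_error(micro_config(use_text_encoder = TRUE, use_metadata = FALSE,
                            use_mgca = FALSE), class = "config_error")
  expect_error(neuronet_config(n_classes = 4), class = "config_error")
})

test_that("cross-entropy matches its closed forms and clamps safely", {
  onehot <- rbind(c(1, 0, 0))
  expect_equal(cross_entropy(rbind(c(1, 0, 0)), onehot), 0)
  expect_equal(cross_entropy(rbind(rep(1 / 3, 3)), onehot), log(3),
               tolerance = 1e-12)
  expect_equal(cross_entropy(rbind(c(0.5, 0.25, 0.25)), onehot), log(2),
               tolerance = 1e-12)
  # zero probability on the true class stays finite through the clamp
  expect_lt(cross_entropy(rbind(c(0, 1, 0)), onehot), 28)
  expect_error(cross_entropy(rbind(c(0.5, 0.5, 0)), rbind(c(0.4, 0.3, 0.3))),
               class = "loss_error")
  # batch mean over two rows
  p2 <- rbind(c(1, 0, 0), rep(1 / 3, 3))
  y2 <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(cross_entropy(p2, y2), log(3) / 2, tolerance = 1e-10)
})

test_that("analytic gradients agree with finite differences across layer types", {
  set.seed(52)
  cfg <- micro_config()
  m <- build_neuronet(cfg, seed = 7)
  B <- 2
  imgs <- array(runif(16 * 16 * B), c(16, 16, B))
  txt <- array(rnorm(8 * 5 * B), c(8, 5, B))
  y <- neuronetad:::onehot_labels(c("NC", "AD"), cfg$classes)
  loss_fn <- function() {
    fw <- neuronet_forward(m, imgs, txt, training = TRUE)
    cross_entropy(fw$prob, y)
  }
  fw <- neuronet_forward(m, imgs, txt, training = TRUE)
  neuronetad:::zero_model_grads(m)
  neuronetad:::neuronet_backward(m, (fw$prob - y) / B)
  lys <- neuronetad:::model_layers(m)
  # spot-check a few parameters in structurally different layers:
  # stem conv, a CBAM, the MGCA block, the text projection, the classifier
  types <- vapply(lys, function(l) l$type, "")
  picks <- c(which(types == "conv")[1], which(types == "bn")[1],
             which(types == "cbam")[1], which(types == "mgca"),
             which(types == "linear"))
  h <- 1e-5
  for (li in picks) {
    ly <- lys[[li]]
    for (nm in names(ly$par)[1:min(2, length(ly$par))]) {
      j <- sample(length(ly$par[[nm]]), 1)
      old <- ly$par[[nm]][j]
      ly$par[[nm]][j] <- old + h; lp <- loss_fn()
      ly$par[[nm]][j] <- old - h; lm <- loss_fn()
      ly$par[[nm]][j] <- old
      num <- (lp - lm) / (2 * h)
      expect_equal(ly$grad[[nm]][j], num, tolerance = 1e-3,
                   label = sprintf("%s$%s[%d]", ly$type, nm, j))
    }
  }
})

test_that("zeroing the fusion output projection recovers the image-only network bit-exactly", {
  cfgF <- micro_config()
  cfgI <- micro_config(use_mgca = FALSE, use_metadata = FALSE,
                       use_feature_selection = FALSE,
                       use_text_encoder = FALSE)
  mf <- build_neuronet(cfgF, seed = 5)
  mi <- build_neuronet(cfgI, seed = 5)
  lf <- neuronetad:::model_layers(mf)
  li <- neuronetad:::model_layers(mi)
  types <- vapply(lf, function(l) l$type, "")
  keep <- which(!types %in% c("mgca", "linear") | seq_along(lf) == length(lf))
  keep <- setdiff(seq_along(lf), c(which(types == "mgca"),
                                   which(types == "linear")[1]))
  # the shared layers (backbone + classifier) in order
  stopifnot(length(keep) == length(li))
  for (i in seq_along(li)) {
    li[[i]]$par <- lf[[keep[i]]]$par
    li[[i]]$buf$running_mean <- lf[[keep[i]]]$buf$running_mean
    li[[i]]$buf$running_var <- lf[[keep[i]]]$buf$running_var
  }
  mf$mgca$par$Wo[] <- 0
  mf$mgca$par$bo[] <- 0
  set.seed(53)
  imgs <- array(runif(16 * 16 * 3), c(16, 16, 3))
  txt <- array(rnorm(8 * 5 * 3), c(8, 5, 3))
  expect_identical(neuronet_forward(mf, imgs, txt)$logits,
                   neuronet_forward(mi, imgs)$logits)
})

test_that("early stopping halts exactly at best epoch + patience", {
  seq1 <- c(50, 60, 70, 80, 90, rep(85, 40))  # last improvement at epoch 5
  r <- early_stopping_epochs(seq1, patience = 20)
  expect_equal(r$best_epoch, 5)
  expect_equal(r$stop_epoch, 25)
  # strictly increasing sequence never stops early
  r2 <- early_stopping_epochs(1:30, patience = 5)
  expect_equal(r2$stop_epoch, 30)
  expect_equal(r2$best_epoch, 30)
  # plateau counts from the first of the ties
  r3 <- early_stopping_epochs(c(1, 2, 2, 2, 2), patience = 3)
  expect_equal(r3$best_epoch, 2)
  expect_equal(r3$stop_epoch, 5)
})

test_that("the training loop obeys the injected validation sequence", {
  co <- micro_cohort(n = 8, seed = 54, slices = 2)
  ids <- vapply(co, `[[`, "", "subject_id")
  ovr <- c(50, 60, 70, 80, 90, rep(85, 40))
  fit <- train_neuronet(co, ids[1:6], ids[7:8], micro_config(),
                        training_config(max_epochs = 40, patience = 20,
                                        seed = 1, batch_size = 8),
                        feature_ranking = micro_ranking(),
                        val_accuracy_override = ovr)
  expect_equal(fit$epochs_run, 25)
  expect_equal(fit$best_epoch, 5)
  expect_equal(fit$best_val_accuracy, 90)
  expect_equal(fit$history$val_accuracy, ovr[1:25])
})

test_that("training is deterministic, leak-checked, and returns the best checkpoint", {
  co <- micro_cohort(n = 10, seed = 55, slices = 2, separation = 2)
  ids <- vapply(co, `[[`, "", "subject_id")
  tc <- training_config(max_epochs = 2, patience = 2, seed = 2, batch_size = 8)
  f1 <- train_neuronet(co, ids[1:8], ids[9:10], micro_config(), tc,
                       feature_ranking = micro_ranking())
  f2 <- train_neuronet(co, ids[1:8], ids[9:10], micro_config(), tc,
                       feature_ranking = micro_ranking())
  expect_equal(f1$history, f2$history, tolerance = 1e-12)
  expect_equal(f1$best_val_accuracy, max(f1$history$val_accuracy))
  expect_error(train_neuronet(co, ids[1:8], ids[8:10], micro_config(), tc),
               class = "leakage_error")
})

test_that("run artifacts (history, manifest, checkpoint) are written", {
  fx <- trained_tiny()
  dir <- withr::local_tempdir()
  save_run(fx$fit, dir)
  expect_true(file.exists(file.path(dir, "history.csv")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$best_epoch, fx$fit$best_epoch)
  expect_equal(length(man$selected), 5)
  ck <- readRDS(file.path(dir, "checkpoint.rds"))
  expect_equal(ck$classes, c("NC", "MCI", "AD"))
})

test_that("training loss decreases over the first epochs of the learnability run", {
  fx <- trained_tiny()
  hist <- fx$fit$history
  expect_gt(nrow(hist), 2)
  expect_lt(hist$train_loss[3], hist$train_loss[1])
  expect_equal(fx$fit$best_val_accuracy, max(hist$val_accuracy))
})
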