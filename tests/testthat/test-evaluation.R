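# Metrics, fold statistics, ablation machinery, activation maps.

test_that("perfect predictions give diagonal confusion and 100% everywhere", {
  r <- compute_metrics(c("NC", "MCI", "AD", "AD"), c("NC", "MCI", "AD", "AD"),
                       c("NC", "MCI", "AD"))
  expect_equal(sum(diag(r$confusion)), 4)
  expect_equal(r$overall$accuracy, 100)
  expect_true(all(r$per_class$precision == 100))
  expect_true(all(r$per_class$f1 == 100))
})

test_that("the two-class worked confusion matrix reproduces hand-computed rates", {
  # confusion [[8,2],[1,9]]: class-0 precision 8/9, recall 80%, F1 84.21%
  truth <- rep(c("a", "b"), c(10, 10))
  pred <- c(rep("a", 8), rep("b", 2), "a", rep("b", 9))
  r <- compute_metrics(pred, truth, c("a", "b"))
  expect_equal(r$per_class$precision[1], 100 * 8 / 9, tolerance = 1e-9)
  expect_equal(r$per_class$recall[1], 80)
  expect_equal(r$per_class$f1[1], 84.21, tolerance = 1e-2)
  # micro accuracy is the confusion trace over the total
  expect_equal(r$overall$accuracy, 100 * sum(diag(r$confusion)) / 20)
})

test_that("macro metrics are invariant under class relabeling", {
  set.seed(61)
  truth <- sample(c("NC", "MCI", "AD"), 60, replace = TRUE)
  pred <- sample(c("NC", "MCI", "AD"), 60, replace = TRUE)
  a <- compute_metrics(pred, truth, c("NC", "MCI", "AD"))
  relab <- c(NC = "AD", MCI = "NC", AD = "MCI")
  b <- compute_metrics(unname(relab[pred]), unname(relab[truth]),
                       c("NC", "MCI", "AD"))
  expect_equal(a$overall$f1, b$overall$f1, tolerance = 1e-9)
  expect_equal(a$overall$accuracy, b$overall$accuracy, tolerance = 1e-9)
})

test_that("an absent class is flagged, not fatal", {
  r <- compute_metrics(c("NC", "NC"), c("NC", "NC"), c("NC", "MCI", "AD"))
  expect_true(any(grepl("absent", r$flags)))
  expect_equal(r$overall$accuracy, 100)
})

test_that("one-vs-rest AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(62)
  truth <- sample(c("NC", "AD"), 50, replace = TRUE)
  prob <- matrix(runif(100), 50, 2, dimnames = list(NULL, c("NC", "AD")))
  prob <- prob / rowSums(prob)
  r <- compute_metrics(ifelse(prob[, 1] > 0.5, "NC", "AD"), truth,
                       c("NC", "AD"), prob = prob)
  ref <- as.numeric(pROC::auc(pROC::roc(truth == "NC", prob[, "NC"],
                                        quiet = TRUE,
                                        direction = "<", levels = c(FALSE, TRUE))))
  expect_equal(r$per_class$auc[1], ref, tolerance = 1e-9)
})

test_that("the paired t-test matches the reference distribution and flags degeneracies", {
  b <- c(10, 20, 30, 40, 50)
  a <- b + 1:5                     # differences 1..5
  r <- paired_t_test(a, b)
  expect_equal(r$t, 4.2426, tolerance = 1e-4)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 0.0132, tolerance = 5e-3)
  # cross-check against the stock implementation
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-9)
  # identical inputs: flagged, p = 1
  rd <- paired_t_test(b, b)
  expect_equal(rd$p_value, 1)
  expect_match(rd$flag, "identical")
  # constant nonzero differences: flagged, p = 0
  rz <- paired_t_test(b + 2, b)
  expect_equal(rz$p_value, 0)
  # antisymmetry
  r2 <- paired_t_test(b, a)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p_value, r$p_value)
  expect_error(paired_t_test(1:4, 1:5), class = "evaluation_error")
})

test_that("fold summaries follow the t-interval closed form", {
  s <- fold_summary(c(92, 93, 94, 95, 96))
  expect_equal(s$mean, 94)
  expect_equal(s$sd, 1.5811, tolerance = 1e-4)
  expect_equal(s$ci_lower, 92.04, tolerance = 1e-2)
  expect_equal(s$ci_upper, 95.96, tolerance = 1e-2)
  # constant accuracies: zero sd, zero-width interval
  sc <- fold_summary(rep(90, 5))
  expect_equal(sc$sd, 0)
  expect_equal(sc$ci_upper - sc$ci_lower, 0)
})

test_that("cross-validation emits one report per fold and never touches held-out subjects", {
  co <- micro_cohort(n = 15, seed = 63, slices = 2, separation = 2)
  plan <- assign_splits(co, 0.2, 3, seed = 63)
  cv <- run_cross_validation(co, plan, micro_config(),
                             training_config(max_epochs = 1, patience = 1,
                                             seed = 1, batch_size = 8),
                             feature_ranking = micro_ranking())
  expect_length(cv$fold_reports, 3)
  expect_length(cv$fold_accuracy, 3)
  expect_equal(cv$summary$mean, mean(cv$fold_accuracy))
  expect_length(cv$history, 3)
})

test_that("the head-count ablation runs 1/2/4/8 and FLOPs increase strictly", {
  co <- micro_cohort(n = 12, seed = 64, slices = 2, separation = 2)
  plan <- assign_splits(co, 0.25, 3, seed = 64)
  ab <- run_ablation(co, plan, micro_config(),
                     training_config(max_epochs = 1, patience = 1, seed = 1,
                                     batch_size = 8),
                     which = "heads", feature_ranking = micro_ranking())
  expect_equal(ab$variant, paste0("heads_", c(1, 2, 4, 8)))
  expect_true(all(diff(ab$flops_g) > 0))
  expect_true(all(is.finite(ab$accuracy)))
})

test_that("ablation grids share partitions and the no-fusion cell is the image-only model", {
  grid <- neuronetad:::ablation_grid(micro_config(), "leave_one_out")
  expect_named(grid, c("full", "no_cbam", "no_mgca", "no_fs", "no_te",
                       "no_fusion"))
  nf <- grid$no_fusion
  expect_false(nf$use_cbam || nf$use_mgca || nf$use_metadata)
  add <- neuronetad:::ablation_grid(micro_config(), "additive")
  expect_false(add$base$use_cbam)
  expect_true(add$cbam$use_cbam && !add$cbam$use_mgca)
  expect_true(add$full$use_text_encoder)
})

test_that("FLOPs estimates scale with resolution and component toggles", {
  big <- flops_estimate(neuronet_config())
  tiny <- flops_estimate(neuronet_config(tiny = TRUE))
  expect_gt(big, tiny)
  no_mgca <- flops_estimate(neuronet_config(use_mgca = FALSE,
                                            use_metadata = FALSE,
                                            use_feature_selection = FALSE,
                                            use_text_encoder = FALSE))
  expect_gt(flops_estimate(neuronet_config()), no_mgca)
})

test_that("activation maps are normalized, full-size, and localize disease evidence", {
  fx <- trained_tiny()
  by_id <- setNames(fx$cohort, vapply(fx$cohort, `[[`, "", "subject_id"))
  msk <- brain_mask(32)
  inside <- 0; total <- 0; diffs <- numeric(0)
  for (sid in fx$plan$held_out) {
    s <- by_id[[sid]]
    for (k in c(1, 5, 9)) {
      cam <- class_activation_map(fx$fit, s$slices[[k]], s$label,
                                  metadata = s$metadata)
      expect_equal(dim(cam), c(32, 32))
      expect_true(all(cam >= 0 & cam <= 1))
      d <- mean(cam[msk]) - mean(cam[!msk])
      diffs <- c(diffs, d)
      if (s$label != "NC") {
        total <- total + 1
        inside <- inside + (d > 0)
      }
    }
  }
  # disease-class slices localize inside the brain in >= 90% of cases;
  # across all classes the heat is higher inside on average
  expect_gte(inside / total, 0.9)
  expect_gt(mean(diffs), 0)
  expect_error(class_activation_map(fx$fit, by_id[[1]]$slices[[1]], "XX"),
               class = "evaluation_error")
})
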