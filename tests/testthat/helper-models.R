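# Shared fixtures built once per test run.

# A tiny model trained to convergence on a well-separated synthetic cohort,
# reused by the activation-map and checkpoint tests.
trained_tiny <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cc <- cohort_config(n_subjects = 40, image_size = 32, seed = 7,
                          separation = 2)
      cohort <- generate_cohort(cc)
      plan <- assign_splits(cohort, held_out_fraction = 0.2, n_folds = 4,
                            seed = 7)
      mem <- fold_members(plan, 1)
      fit <- train_neuronet(cohort, mem$train, mem$validation,
                            neuronet_config(tiny = TRUE),
                            training_config(max_epochs = 5, patience = 5,
                                            seed = 7))
      cache <<- list(fit = fit, cohort = cohort, plan = plan)
    }
    cache
  }
})

# Micro configuration: small enough for gradient checks and fast train-loop
# mechanics, still exercising every component.
micro_config <- function(...) {
  neuronet_config(tiny = TRUE, image_size = 16, widths = c(4, 8, 8, 8),
                  embed_dim = 16, text_max_len = 8, text_hidden = 5,
                  cbam_reduction = 2, n_heads = 2, dropout = 0, ...)
}

micro_cohort <- function(n = 12, seed = 3, image_size = 16, slices = 2, ...) {
  generate_cohort(cohort_config(n_subjects = n, image_size = image_size,
                                slices_per_subject = slices, seed = seed, ...))
}

# Continuous-valued features that cannot degenerate to zero variance on the
# handful of subjects micro tests use; passed as a precomputed ranking.
micro_ranking <- function() {
  list(selected = c("MMSE", "FAQ-Score", "Age", "Weight", "GDSCALE"))
}
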