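# Subject-level splitting, standardization, augmentation, readers.

test_that("the 200-subject design reproduces the reference protocol exactly", {
  co <- generate_cohort(cohort_config(n_subjects = 200, image_size = 16,
                                      seed = 1), render_images = FALSE)
  plan <- assign_splits(co, held_out_fraction = 0.2, n_folds = 5, seed = 4)
  labs <- setNames(vapply(co, `[[`, "", "label"),
                   vapply(co, `[[`, "", "subject_id"))
  expect_length(plan$held_out, 40)
  expect_equal(as.integer(table(labs[plan$held_out])[c("NC", "MCI", "AD")]),
               c(12, 14, 14))
  # every fold: exactly 32 validation subjects, 128 training subjects
  for (f in 1:5) {
    mem <- fold_members(plan, f)
    expect_length(mem$validation, 32)
    expect_length(mem$train, 128)
  }
  # per-class fold sizes differ by at most 1
  for (cl in c("NC", "MCI", "AD")) {
    sizes <- vapply(plan$folds, function(ids) sum(labs[ids] == cl), 0)
    expect_lte(max(sizes) - min(sizes), 1)
  }
})

test_that("every subject appears in exactly one partition", {
  co <- generate_cohort(cohort_config(n_subjects = 53, image_size = 16,
                                      seed = 2), render_images = FALSE)
  plan <- assign_splits(co, 0.2, 5, seed = 11)
  ids <- vapply(co, `[[`, "", "subject_id")
  # exhaustive membership count oracle
  membership <- vapply(ids, function(id) {
    sum(id %in% plan$held_out,
        vapply(plan$folds, function(f) id %in% f, TRUE))
  }, 0)
  expect_true(all(membership == 1))
  expect_length(intersect(plan$held_out, unlist(plan$folds)), 0)
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(plan$folds[[i]], plan$folds[[j]]), 0)
})

test_that("split plans are deterministic in the seed and fold-balanced", {
  co <- generate_cohort(cohort_config(n_subjects = 47, image_size = 16,
                                      seed = 3), render_images = FALSE)
  p1 <- assign_splits(co, 0.25, 4, seed = 5)
  p2 <- assign_splits(co, 0.25, 4, seed = 5)
  expect_identical(p1, p2)
  p3 <- assign_splits(co, 0.25, 4, seed = 6)
  expect_false(identical(p1$held_out, p3$held_out))
  sizes <- vapply(p1$folds, length, 0)
  expect_lte(max(sizes) - min(sizes), 3)  # <= number of classes
})

test_that("a class smaller than the fold count is a protocol error", {
  co <- generate_cohort(cohort_config(n_subjects = 12, image_size = 16,
                                      seed = 4), render_images = FALSE)
  expect_error(assign_splits(co, 0.2, 5, seed = 1), class = "protocol_error")
  expect_error(assign_splits(co, 1.2, 2, seed = 1), class = "protocol_error")
})

test_that("split plans round-trip through JSON", {
  co <- generate_cohort(cohort_config(n_subjects = 20, image_size = 16,
                                      seed = 5), render_images = FALSE)
  plan <- assign_splits(co, 0.2, 4, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_split_plan(plan, path)
  back <- read_split_plan(path)
  expect_equal(back$held_out, plan$held_out)
  expect_equal(back$folds, plan$folds)
  expect_equal(back$seed, plan$seed)
})

test_that("standardizer matches the population-sd convention", {
  p <- fit_standardizer(matrix(c(0, 2), ncol = 1))
  expect_equal(as.numeric(p$mean), 1)
  expect_equal(as.numeric(p$sd), 1)
  expect_equal(as.numeric(apply_standardizer(matrix(c(0, 2), ncol = 1), p)),
               c(-1, 1))
})

test_that("standardized training columns have mean 0 and unit sd; held-out reuses training parameters", {
  set.seed(9)
  X <- matrix(rnorm(100 * 5, mean = 3, sd = 2), 100, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  p <- fit_standardizer(X)
  Z <- apply_standardizer(X, p)
  expect_true(all(abs(colMeans(Z)) < 1e-9))
  expect_true(all(abs(sqrt(colMeans(sweep(Z, 2, colMeans(Z))^2)) - 1) < 1e-9))
  held <- matrix(rnorm(20 * 5, mean = 10), 20, 5)
  Zh <- apply_standardizer(held, p)
  expect_gt(mean(colMeans(Zh)), 1)  # held-out mean is not re-centred
})

test_that("zero-variance features are refused by name", {
  X <- cbind(a = rnorm(10), b = rep(2, 10))
  err <- tryCatch(fit_standardizer(X), error = identity)
  expect_s3_class(err, "protocol_error")
  expect_match(conditionMessage(err), "b")
})

test_that("augmentation honours the identity, involution and scaling contracts", {
  set.seed(10)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(augment_slice(img, augmentation_config(enabled = FALSE)),
                   img)
  f <- function(x) augment_slice(x, augmentation_config(),
                                 force = list(flip = TRUE, angle = 0,
                                              scale = 1))
  expect_identical(f(f(img)), img)
  # with scale only, output is the clamped elementwise product
  s <- 1.07
  out <- augment_slice(img, augmentation_config(),
                       force = list(flip = FALSE, angle = 0, scale = s))
  expect_equal(out, pmin(pmax(img * s, 0), 1), tolerance = 1e-12)
  # rotation keeps values clamped and fills corners with background
  rot <- augment_slice(img + 0.5, augmentation_config(),
                       force = list(flip = FALSE, angle = 9, scale = 1))
  expect_true(all(rot >= 0 & rot <= 1))
  expect_lt(rot[1, 1], 0.5)  # corner exposed by the rotation is dark
})

test_that("augmented draws stay within the configured ranges", {
  set.seed(11)
  img <- matrix(runif(16 * 16), 16, 16)
  cfgs <- augmentation_config(horizontal_flip_prob = 1,
                              rotation_limit_degrees = 5,
                              intensity_scale_range = c(0.95, 1.05))
  for (i in 1:20) {
    out <- augment_slice(img, cfgs)
    expect_true(all(out >= 0 & out <= 1))
  }
  expect_error(augmentation_config(horizontal_flip_prob = 2),
               class = "config_error")
  expect_error(augmentation_config(intensity_scale_range = c(-1, 1)),
               class = "config_error")
})

test_that("NIfTI volumes yield equally spaced central slices in [0,1]", {
  skip_if_not_installed("RNifti")
  vol <- array(seq(0, 100, length.out = 24 * 24 * 30), c(24, 24, 30))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  slices <- read_nifti_slices(path, n_slices = 10, image_size = 16)
  expect_length(slices, 10)
  expect_true(all(vapply(slices, function(m)
    all(dim(m) == c(16, 16)) && all(m >= 0 & m <= 1), TRUE)))
  # intensities increase along z in the synthetic volume, so slice means do
  means <- vapply(slices, mean, 0)
  expect_true(all(diff(means) > 0))
})
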