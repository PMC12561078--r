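# Synthetic cohort generator: counts, determinism, ranges, class signal.

test_that("class counts follow largest-remainder rounding and conserve totals", {
  cfg <- cohort_config(n_subjects = 200, image_size = 16, seed = 1)
  expect_identical(cfg$class_counts,
                   c(NC = 60L, MCI = 70L, AD = 70L))
  co <- generate_cohort(cfg, render_images = FALSE)
  expect_length(co, 200)
  labs <- table(vapply(co, `[[`, "", "label"))
  expect_equal(as.integer(labs[c("NC", "MCI", "AD")]), c(60, 70, 70))
  # awkward proportions still conserve the total
  cfg2 <- cohort_config(n_subjects = 17,
                        class_proportions = c(1 / 3, 1 / 3, 1 / 3),
                        image_size = 16, seed = 1)
  expect_equal(sum(cfg2$class_counts), 17L)
  expect_true(max(cfg2$class_counts) - min(cfg2$class_counts) <= 1)
})

test_that("slice totals equal n_subjects x slices_per_subject", {
  co <- generate_cohort(cohort_config(n_subjects = 9, image_size = 16,
                                      slices_per_subject = 4, seed = 2))
  expect_equal(sum(vapply(co, function(s) length(s$slices), 0L)), 36)
  expect_true(all(vapply(co, function(s) length(s$slices) == 4, TRUE)))
  ids <- vapply(co, `[[`, "", "subject_id")
  expect_false(anyDuplicated(ids) > 0)
})

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- cohort_config(n_subjects = 6, image_size = 16, seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(class_proportions = c(0.5, 0.4, 0.2)),
               class = "config_error")
  expect_error(cohort_config(n_subjects = 2), class = "config_error")
  expect_error(cohort_config(separation = -1), class = "config_error")
  expect_error(render_slice("NC", 10, 16, n_slices = 10),
               class = "config_error")
})

test_that("metadata fields respect their clinical ranges", {
  set.seed(4)
  for (lab in c("NC", "MCI", "AD")) {
    for (i in 1:50) {
      r <- sample_metadata(lab, separation = 3)
      expect_true(r$MMSE >= 0 && r$MMSE <= 30)
      expect_true(r$GDSCALE >= 0 && r$GDSCALE <= 15)
      expect_true(r$`Global-CDR` %in% c(0, 0.5, 1, 2, 3))
      expect_true(r$`FAQ-Score` >= 0 && r$`FAQ-Score` <= 30)
      expect_true(r$`NPIQ-Score` >= 0)
      expect_true(r$`APOE-A1` %in% c(2, 3, 4) && r$`APOE-A2` %in% c(2, 3, 4))
      expect_false(anyNA(unlist(r)))
    }
  }
})

test_that("class-conditional metadata means order NC > MCI > AD on MMSE and reverse on FAQ", {
  set.seed(5)
  draw_means <- function(lab, n = 400) {
    recs <- replicate(n, sample_metadata(lab, separation = 1),
                      simplify = FALSE)
    c(mmse = mean(vapply(recs, `[[`, 0, "MMSE")),
      faq = mean(vapply(recs, function(r) r$`FAQ-Score`, 0)))
  }
  m <- vapply(c("NC", "MCI", "AD"), draw_means, c(mmse = 0, faq = 0))
  expect_true(m["mmse", "NC"] > m["mmse", "MCI"])
  expect_true(m["mmse", "MCI"] > m["mmse", "AD"])
  expect_true(m["faq", "NC"] < m["faq", "MCI"])
  expect_true(m["faq", "MCI"] < m["faq", "AD"])
})

test_that("separation 0 removes class signal from the metadata", {
  # two-sample t-test p-values on MMSE between NC and AD should be uniform
  # under the null; check with a Kolmogorov-Smirnov test over seeds
  ps <- vapply(1:60, function(s) {
    set.seed(s)
    nc <- vapply(1:25, function(i) sample_metadata("NC", 0)$MMSE, 0)
    ad <- vapply(1:25, function(i) sample_metadata("AD", 0)$MMSE, 0)
    stats::t.test(nc, ad)$p.value
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("slices are clamped to [0,1] and the ventricle grows with severity", {
  set.seed(6)
  imgs_nc <- replicate(60, render_slice("NC", 4, 32, separation = 1), simplify = FALSE)
  imgs_ad <- replicate(60, render_slice("AD", 4, 32, separation = 1), simplify = FALSE)
  expect_true(all(vapply(imgs_nc, function(m) all(m >= 0 & m <= 1), TRUE)))
  dark <- function(m) sum(m < 0.3 & brain_mask(32))
  expect_gt(mean(vapply(imgs_ad, dark, 0)), mean(vapply(imgs_nc, dark, 0)))
})

test_that("separation 0 makes class mean images indistinguishable", {
  set.seed(7)
  mean_img <- function(lab, n = 300) {
    acc <- matrix(0, 24, 24)
    for (i in seq_len(n)) acc <- acc + render_slice(lab, 4, 24, separation = 0)
    acc / n
  }
  d <- max(abs(mean_img("NC") - mean_img("AD")))
  expect_lt(d, 0.06)  # sampling noise only: ~4 sd of the pixel mean difference
})

test_that("higher separation does not reduce metadata class separability", {
  # simple discriminant: midpoint threshold on MMSE between NC and AD
  acc_at <- function(sep, n = 500) {
    set.seed(123)
    nc <- vapply(seq_len(n), function(i) sample_metadata("NC", sep)$MMSE, 0)
    ad <- vapply(seq_len(n), function(i) sample_metadata("AD", sep)$MMSE, 0)
    thr <- (mean(nc) + mean(ad)) / 2
    (sum(nc > thr) + sum(ad <= thr)) / (2 * n)
  }
  a <- vapply(c(0, 0.5, 1, 2), acc_at, 0)
  expect_true(all(diff(a) > -0.03))  # non-decreasing up to sampling noise
  expect_gt(a[4], 0.9)
})

test_that("cohort directories round-trip through the writer and reader", {
  dir <- withr::local_tempdir()
  co <- micro_cohort(n = 4, seed = 8)
  write_cohort(co, dir, config = cohort_config(n_subjects = 4,
                                               image_size = 16, seed = 8))
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "cohort.json")))
  back <- read_cohort(dir)
  expect_equal(length(back), 4)
  expect_equal(vapply(back, `[[`, "", "subject_id"),
               vapply(co, `[[`, "", "subject_id"))
  expect_equal(vapply(back, `[[`, "", "label"),
               vapply(co, `[[`, "", "label"))
  # PNG quantizes to 8 bits; pixel round trip within half a quantum
  expect_lt(max(abs(back[[1]]$slices[[1]] - co[[1]]$slices[[1]])), 1 / 255)
  expect_equal(as.numeric(back[[2]]$metadata$MMSE),
               as.numeric(co[[2]]$metadata$MMSE))
})
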