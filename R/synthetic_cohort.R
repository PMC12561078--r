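# Seeded synthetic cohort generator.
#
# Emulates the statistical structure the classifier assumes: per subject, a
# fixed number of 2D grayscale "brain" slices whose central ventricle area
# grows with disease severity, and a clinical metadata record whose
# class-conditional distributions shift along NC -> MCI -> AD. A `separation`
# knob scales both signals; at separation 0 classes are exchangeable.

AD_CLASSES <- c("NC", "MCI", "AD")

METADATA_FIELDS <- c("Weight", "Age", "APOE-A1", "APOE-A2", "MMSE",
                     "GDSCALE", "Global-CDR", "FAQ-Score", "NPIQ-Score")

#' Configuration for a synthetic cohort
#'
#' @param n_subjects number of subjects (>= 3).
#' @param class_proportions length-3 numeric (NC, MCI, AD) summing to 1.
#' @param slices_per_subject slices generated per subject (default 10).
#' @param image_size pixels per side of each square slice (default 224; tests
#'   typically use 32 or 16).
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @param separation non-negative signal strength shared by images and
#'   metadata; `image_separation` / `metadata_separation` override it per
#'   modality (used e.g. to build cohorts whose images are pure noise while
#'   metadata carries class signal).
#' @param image_separation,metadata_separation per-modality overrides.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 200,
                          class_proportions = c(NC = 0.30, MCI = 0.35, AD = 0.35),
                          slices_per_subject = 10,
                          image_size = 224,
                          seed = 1,
                          separation = 1,
                          image_separation = NULL,
                          metadata_separation = NULL) {
  if (length(class_proportions) != 3 || any(class_proportions < 0))
    nn_stop("config_error", "class_proportions must be 3 non-negative reals")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    nn_stop("config_error", "class_proportions must sum to 1 (got %.12f)",
            sum(class_proportions))
  if (n_subjects < 3)
    nn_stop("config_error", "n_subjects must be >= 3")
  if (slices_per_subject < 1 || image_size < 8)
    nn_stop("config_error", "slices_per_subject >= 1 and image_size >= 8 required")
  if (separation < 0)
    nn_stop("config_error", "separation must be >= 0")
  cfg <- list(n_subjects = as.integer(n_subjects),
              class_proportions = setNames(as.numeric(class_proportions), AD_CLASSES),
              slices_per_subject = as.integer(slices_per_subject),
              image_size = as.integer(image_size),
              seed = as.integer(seed),
              separation = separation,
              image_separation = image_separation %||% separation,
              metadata_separation = metadata_separation %||% separation)
  counts <- largest_remainder_counts(cfg$n_subjects, cfg$class_proportions)
  if (any(counts == 0 & cfg$class_proportions > 0))
    nn_stop("config_error",
            "n_subjects = %d is too small to populate every class with positive proportion",
            cfg$n_subjects)
  cfg$class_counts <- counts
  class(cfg) <- "cohort_config"
  cfg
}

# Round n * p to integers that sum to n, giving the leftover units to the
# largest fractional remainders (ties broken by class order).
largest_remainder_counts <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    take <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  setNames(as.integer(base), names(p))
}

## ---- metadata --------------------------------------------------------------

# Class-conditional metadata model. Continuous instruments are Gaussian with a
# class mean pulled away from a shared baseline proportionally to
# `separation`, then rounded/clamped to the instrument's scale. Global-CDR and
# the APOE alleles are categorical mixtures between a shared baseline and a
# class-specific target.
META_MODEL <- list(
  MMSE    = list(base = 25, target = c(NC = 29, MCI = 26, AD = 20), sd = 2,
                 lo = 0, hi = 30, int = TRUE),
  `FAQ-Score` = list(base = 9, target = c(NC = 2, MCI = 8, AD = 18), sd = 4,
                 lo = 0, hi = 30, int = TRUE),
  GDSCALE = list(base = 4, target = c(NC = 2, MCI = 4, AD = 6), sd = 2,
                 lo = 0, hi = 15, int = TRUE),
  `NPIQ-Score` = list(base = 4, target = c(NC = 1, MCI = 4, AD = 9), sd = 3,
                 lo = 0, hi = 36, int = TRUE),
  Age     = list(base = 73, target = c(NC = 71.5, MCI = 73, AD = 74.5), sd = 6,
                 lo = 55, hi = 95, int = FALSE),
  Weight  = list(base = 75, target = c(NC = 77, MCI = 75, AD = 73), sd = 10,
                 lo = 40, hi = 130, int = FALSE)
)

CDR_LEVELS <- c(0, 0.5, 1, 2, 3)
CDR_BASE <- c(0.40, 0.33, 0.17, 0.07, 0.03)
CDR_TARGET <- list(NC = c(0.90, 0.08, 0.02, 0.00, 0.00),
                   MCI = c(0.15, 0.70, 0.13, 0.02, 0.00),
                   AD = c(0.02, 0.18, 0.50, 0.20, 0.10))

APOE_LEVELS <- c(2, 3, 4)
APOE_BASE_P4 <- 0.25
APOE_TARGET_P4 <- c(NC = 0.10, MCI = 0.25, AD = 0.42)

#' Draw one class-conditioned metadata record
#'
#' Uses the current R RNG state; callers control determinism with `set.seed`.
#'
#' @param label one of `"NC"`, `"MCI"`, `"AD"`.
#' @param separation non-negative signal strength; 0 makes all classes share
#'   one distribution.
#' @return named list with the nine clinical fields, all within range.
#' @export
sample_metadata <- function(label, separation = 1) {
  label <- match.arg(label, AD_CLASSES)
  s <- separation
  w <- min(s, 1)   # mixture weight for categorical fields
  rec <- list()
  for (f in names(META_MODEL)) {
    m <- META_MODEL[[f]]
    mu <- m$base + s * (m$target[[label]] - m$base)
    v <- rnorm(1, mean = mu, sd = m$sd)
    v <- min(max(v, m$lo), m$hi)
    rec[[f]] <- if (m$int) as.integer(round(v)) else round(v, 1)
  }
  p_cdr <- (1 - w) * CDR_BASE + w * CDR_TARGET[[label]]
  rec[["Global-CDR"]] <- CDR_LEVELS[sample.int(5, 1, prob = p_cdr)]
  p4 <- (1 - w) * APOE_BASE_P4 + w * APOE_TARGET_P4[[label]]
  p_apoe <- c(0.06, 1 - 0.06 - p4, p4)
  rec[["APOE-A1"]] <- APOE_LEVELS[sample.int(3, 1, prob = p_apoe)]
  rec[["APOE-A2"]] <- APOE_LEVELS[sample.int(3, 1, prob = p_apoe)]
  rec[METADATA_FIELDS]
}

## ---- images ----------------------------------------------------------------

#' Nominal brain-ellipse mask for a synthetic slice
#'
#' Logical matrix marking the (un-jittered) brain ellipse; used e.g. to test
#' that class activation maps concentrate on tissue rather than background.
#'
#' @param image_size pixels per side.
#' @return `image_size x image_size` logical matrix.
#' @export
brain_mask <- function(image_size) {
  u <- seq(-1, 1, length.out = image_size)
  xx <- matrix(u, image_size, image_size)
  yy <- t(xx)
  (xx / 0.72)^2 + (yy / 0.86)^2 <= 1
}

#' Render one synthetic brain slice
#'
#' Produces a procedural axial "brain": a bright tissue ellipse on black
#' background with a central dark ventricle whose area grows with disease
#' severity (when `separation > 0`), light geometric jitter, and additive
#' Gaussian noise. Values are clamped to `[0, 1]`. Uses the current RNG state.
#'
#' @param label class label.
#' @param slice_index 0-based slice index in `[0, n_slices)`; modulates
#'   structure size as a crude stand-in for the slice's axial position.
#' @param image_size pixels per side.
#' @param separation image signal strength (0 removes all class dependence).
#' @param n_slices slices per subject (for the axial-position modulation).
#' @return `image_size x image_size` numeric matrix in `[0, 1]`.
#' @export
render_slice <- function(label, slice_index, image_size = 224, separation = 1,
                         n_slices = 10) {
  label <- match.arg(label, AD_CLASSES)
  if (slice_index < 0 || slice_index >= n_slices)
    nn_stop("config_error", "slice_index must lie in [0, n_slices)")
  sev <- match(label, AD_CLASSES) - 1          # 0, 1, 2
  # axial modulation: central slices are largest
  t0 <- if (n_slices > 1) slice_index / (n_slices - 1) else 0.5
  zf <- 0.85 + 0.6 * t0 * (1 - t0)
  u <- seq(-1, 1, length.out = image_size)
  xx <- matrix(u, image_size, image_size)
  yy <- t(xx)
  cx <- runif(1, -0.03, 0.03); cy <- runif(1, -0.03, 0.03)
  brain <- ((xx - cx) / (0.72 * zf))^2 + ((yy - cy) / (0.86 * zf))^2 <= 1
  img <- matrix(0, image_size, image_size)
  img[brain] <- 0.62
  # ventricle: central dark ellipse, larger with severity when separation > 0
  grow <- 1 + 0.22 * separation * sev
  va <- 0.16 * zf * grow * runif(1, 0.92, 1.08)
  vb <- 0.26 * zf * grow * runif(1, 0.92, 1.08)
  vent <- ((xx - cx) / va)^2 + ((yy - cy) / vb)^2 <= 1
  img[vent & brain] <- 0.12
  img <- img + matrix(rnorm(image_size^2, sd = 0.04), image_size, image_size)
  pmin(pmax(img, 0), 1)
}

## ---- cohort ----------------------------------------------------------------

#' Generate a synthetic cohort
#'
#' Deterministic for a fixed configuration: per-class subject counts follow
#' largest-remainder rounding of `n_subjects * class_proportions`, each
#' subject gets `slices_per_subject` rendered slices and one metadata record.
#'
#' @param config a [cohort_config()].
#' @param render_images set `FALSE` to skip slice rendering (metadata-only
#'   experiments such as repeated feature-selection runs); the returned
#'   subjects then carry an empty `slices` list.
#' @return list of subject records, each with `subject_id`, `label`, `slices`
#'   (list of matrices) and `metadata` (named list).
#' @export
generate_cohort <- function(config, render_images = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  counts <- config$class_counts
  labels <- rep(AD_CLASSES, counts)
  set.seed(config$seed)
  cohort <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    lab <- labels[i]
    md <- sample_metadata(lab, config$metadata_separation)
    slices <- list()
    if (render_images) {
      slices <- lapply(seq_len(config$slices_per_subject) - 1L, function(k)
        render_slice(lab, k, config$image_size, config$image_separation,
                     config$slices_per_subject))
    }
    cohort[[i]] <- list(subject_id = sprintf("S%04d", i),
                        label = lab,
                        slices = slices,
                        metadata = md)
  }
  cohort
}

#' Per-subject metadata table of a cohort
#'
#' @param cohort list of subject records from [generate_cohort()].
#' @return data.frame with `subject_id`, `label` and the nine clinical fields.
#' @export
cohort_metadata <- function(cohort) {
  df <- data.frame(subject_id = vapply(cohort, `[[`, "", "subject_id"),
                   label = vapply(cohort, `[[`, "", "label"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (f in METADATA_FIELDS)
    df[[f]] <- vapply(cohort, function(s) as.numeric(s$metadata[[f]]), 0)
  df
}

cohort_labels <- function(cohort) {
  factor(vapply(cohort, `[[`, "", "label"), levels = AD_CLASSES)
}
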