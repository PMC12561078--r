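# Cohort directory reader/writer and NIfTI slice extraction.
#
# On-disk layout:
#   <dir>/metadata.csv                one row per subject: subject_id, label,
#                                     plus the nine clinical fields
#   <dir>/images/<subject_id>/slice_<k>.png   grayscale slices in [0, 1]
#   <dir>/cohort.json                 generation manifest (config + seed)

#' Write a cohort to a directory
#'
#' @param cohort list of subject records.
#' @param dir output directory (created if missing).
#' @param config optional [cohort_config()] stored in the `cohort.json`
#'   manifest.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- cohort_metadata(cohort)
  write.csv(md, file.path(dir, "metadata.csv"), row.names = FALSE)
  imgdir <- file.path(dir, "images")
  for (s in cohort) {
    d <- file.path(imgdir, s$subject_id)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(s$slices))
      png::writePNG(s$slices[[k]], file.path(d, sprintf("slice_%02d.png", k - 1)))
  }
  manifest <- list(package = "neuronetad",
                   n_subjects = length(cohort),
                   slices_per_subject = length(cohort[[1]]$slices))
  if (!is.null(config)) manifest$config <- unclass(config)
  jsonlite::write_json(manifest, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory
#'
#' Counterpart of [write_cohort()]: reads `metadata.csv` and the PNG tree.
#'
#' @param dir cohort directory.
#' @return list of subject records.
#' @export
read_cohort <- function(dir) {
  mdf <- read.csv(file.path(dir, "metadata.csv"), check.names = FALSE,
                  stringsAsFactors = FALSE)
  lapply(seq_len(nrow(mdf)), function(i) {
    sid <- mdf$subject_id[i]
    d <- file.path(dir, "images", sid)
    files <- sort(list.files(d, pattern = "^slice_.*\\.png$", full.names = TRUE))
    slices <- lapply(files, function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3) m <- m[, , 1]
      m
    })
    md <- as.list(mdf[i, METADATA_FIELDS, drop = FALSE])
    names(md) <- METADATA_FIELDS
    list(subject_id = sid, label = mdf$label[i], slices = slices,
         metadata = md)
  })
}

#' Extract equally spaced central slices from a NIfTI volume
#'
#' Takes `n_slices` equally spaced axial slices from the central third of the
#' volume, min-max normalizes intensities over the volume, and resizes each
#' slice to `image_size` pixels per side (bilinear).
#'
#' @param path NIfTI file.
#' @param n_slices number of slices (default 10).
#' @param image_size output side length.
#' @return list of `image_size x image_size` matrices in `[0, 1]`.
#' @export
read_nifti_slices <- function(path, n_slices = 10, image_size = 224) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    nn_stop("io_error", "RNifti is required to read NIfTI volumes")
  vol <- as.array(RNifti::readNifti(path))
  if (length(dim(vol)) < 3)
    nn_stop("io_error", "expected a 3D volume, got %d dims", length(dim(vol)))
  if (length(dim(vol)) > 3) vol <- vol[, , , 1]
  Z <- dim(vol)[3]
  idx <- unique(round(seq(Z / 3, 2 * Z / 3, length.out = n_slices)))
  idx <- pmin(pmax(idx, 1), Z)
  if (length(idx) < n_slices)  # tiny volumes: recycle central indices
    idx <- rep_len(idx, n_slices)
  rng <- range(vol, finite = TRUE)
  den <- if (diff(rng) > 0) diff(rng) else 1
  lapply(idx, function(z) {
    sl <- (vol[, , z] - rng[1]) / den
    resize_bilinear(sl, image_size)
  })
}

# Bilinear resize of a matrix to out x out; delegates to EBImage.
resize_bilinear <- function(m, out) {
  if (nrow(m) == out && ncol(m) == out) return(m)
  r <- EBImage::resize(m, w = out, h = out)
  matrix(pmin(pmax(as.numeric(r), 0), 1), out, out)
}
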