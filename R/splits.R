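# Subject-level stratified splitting: a held-out cut plus k disjoint
# cross-validation folds, all stratified by class. The subject is the atomic
# unit; no slice of a subject ever crosses a partition boundary.

#' Assign subjects to a held-out set and stratified CV folds
#'
#' Per class, `round(held_out_fraction * class size)` subjects are cut for
#' the held-out test set; the remaining pool is dealt into `n_folds` folds by
#' a shuffled round-robin whose starting fold rotates across classes so that
#' per-class remainders land on different folds. For the 200-subject
#' (60/70/70) design with a 20% cut and 5 folds this yields 40 held-out
#' subjects (12/14/14) and five folds of exactly 32 validation / 128 training
#' subjects.
#'
#' @param subjects list of subject records (or a data.frame with
#'   `subject_id` and `label` columns).
#' @param held_out_fraction fraction of each class set aside, in (0, 1).
#' @param n_folds number of CV folds (>= 2).
#' @param seed integer; the plan is deterministic given the seed.
#' @return a `split_plan`: list with `held_out` (character vector of
#'   subject_ids), `folds` (list of `n_folds` character vectors), `seed`.
#' @export
assign_splits <- function(subjects, held_out_fraction = 0.2, n_folds = 5,
                          seed = 1) {
  if (held_out_fraction <= 0 || held_out_fraction >= 1)
    nn_stop("protocol_error", "held_out_fraction must lie in (0, 1)")
  if (n_folds < 2)
    nn_stop("protocol_error", "n_folds must be >= 2")
  if (is.data.frame(subjects)) {
    ids <- subjects$subject_id
    labs <- subjects$label
  } else {
    ids <- vapply(subjects, `[[`, "", "subject_id")
    labs <- vapply(subjects, `[[`, "", "label")
  }
  if (anyDuplicated(ids))
    nn_stop("protocol_error", "subject_ids must be unique")
  set.seed(seed)
  held_out <- character(0)
  folds <- rep(list(character(0)), n_folds)
  offset <- 0L
  for (cl in intersect(AD_CLASSES, unique(labs))) {
    cids <- ids[labs == cl]
    cids <- cids[sample.int(length(cids))]
    n_held <- round(held_out_fraction * length(cids))
    held_out <- c(held_out, cids[seq_len(n_held)])
    pool <- cids[-seq_len(n_held)]
    if (length(pool) < n_folds)
      nn_stop("protocol_error",
              "class %s has only %d CV-pool subjects for %d folds",
              cl, length(pool), n_folds)
    fold_of <- (offset + seq_along(pool) - 1L) %% n_folds + 1L
    for (f in seq_len(n_folds))
      folds[[f]] <- c(folds[[f]], pool[fold_of == f])
    offset <- (offset + length(pool)) %% n_folds
  }
  plan <- list(held_out = held_out, folds = folds, seed = as.integer(seed))
  class(plan) <- "split_plan"
  assert_no_leakage(plan, ids)
  plan
}

# Partition sanity: held-out and folds are pairwise disjoint and (with the
# full id universe) cover every subject exactly once.
assert_no_leakage <- function(plan, all_ids = NULL) {
  parts <- c(list(plan$held_out), plan$folds)
  flat <- unlist(parts)
  if (anyDuplicated(flat))
    nn_stop("leakage_error", "a subject appears in more than one partition")
  if (!is.null(all_ids) && !setequal(flat, all_ids))
    nn_stop("leakage_error", "partitions do not cover the subject set exactly")
  invisible(TRUE)
}

#' Train/validation subject ids for one CV fold
#'
#' @param plan a `split_plan`.
#' @param fold fold index in `1..n_folds`; that fold validates, the others
#'   train. Held-out subjects appear in neither.
#' @return list with `train` and `validation` character vectors.
#' @export
fold_members <- function(plan, fold) {
  stopifnot(fold >= 1, fold <= length(plan$folds))
  list(train = unlist(plan$folds[-fold], use.names = FALSE),
       validation = plan$folds[[fold]])
}

#' Serialize / read a split plan
#'
#' @param plan a `split_plan`.
#' @param path JSON file path.
#' @return `write_split_plan` returns `path` invisibly; `read_split_plan`
#'   returns the plan.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(list(held_out = plan$held_out, folds = plan$folds,
                            seed = plan$seed),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  plan <- list(held_out = as.character(x$held_out),
               folds = lapply(x$folds, as.character),
               seed = as.integer(x$seed))
  class(plan) <- "split_plan"
  plan
}
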