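# Classification metrics. Per-class precision, recall, F1 and one-vs-rest
# accuracy; "overall" rows are macro averages (unweighted means over
# classes), except overall accuracy which is the micro accuracy
# trace(confusion)/total. Division-by-zero cases are reported as 0 and
# flagged rather than crashing. All rates are percentages.

#' Compute a metrics report
#'
#' @param predicted predicted class labels.
#' @param labels true class labels.
#' @param class_names class order for the confusion matrix.
#' @param prob optional `n x K` probability matrix (columns in
#'   `class_names` order) enabling one-vs-rest AUC per class.
#' @return `metrics_report`: list with `confusion` (true rows x predicted
#'   columns), `per_class` data.frame (accuracy, precision, recall, f1, auc;
#'   percent), `overall` (macro precision/recall/F1/AUC + micro accuracy),
#'   and `flags` (character vector of degeneracies).
#' @export
compute_metrics <- function(predicted, labels, class_names, prob = NULL) {
  predicted <- factor(as.character(predicted), levels = class_names)
  labels <- factor(as.character(labels), levels = class_names)
  if (length(predicted) != length(labels))
    nn_stop("evaluation_error", "predicted and labels differ in length")
  cm <- table(true = labels, predicted = predicted)
  K <- length(class_names)
  n <- length(labels)
  flags <- character(0)
  per <- data.frame(class = class_names, accuracy = 0, precision = 0,
                    recall = 0, f1 = 0, auc = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    tp <- cm[k, k]
    fp <- sum(cm[-k, k])
    fn <- sum(cm[k, -k])
    tn <- n - tp - fp - fn
    if (sum(cm[k, ]) == 0)
      flags <- c(flags, sprintf("class %s absent from labels", class_names[k]))
    prec <- if (tp + fp > 0) tp / (tp + fp) else {
      flags <- c(flags, sprintf("precision undefined for %s", class_names[k])); 0
    }
    rec <- if (tp + fn > 0) tp / (tp + fn) else {
      flags <- c(flags, sprintf("recall undefined for %s", class_names[k])); 0
    }
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    per$accuracy[k] <- 100 * (tp + tn) / n
    per$precision[k] <- 100 * prec
    per$recall[k] <- 100 * rec
    per$f1[k] <- 100 * f1
    if (!is.null(prob)) {
      pos <- labels == class_names[k]
      if (any(pos) && any(!pos))
        per$auc[k] <- auc_rank(prob[, k], pos)
    }
  }
  overall <- list(accuracy = 100 * sum(diag(cm)) / n,
                  precision = mean(per$precision),
                  recall = mean(per$recall),
                  f1 = mean(per$f1),
                  auc = if (!is.null(prob)) mean(per$auc, na.rm = TRUE) else NA_real_)
  structure(list(confusion = cm, per_class = per, overall = overall,
                 flags = flags),
            class = "metrics_report")
}

# One-vs-rest AUC by the rank (Mann-Whitney) statistic, ties mid-ranked.
auc_rank <- function(scores, positive) {
  r <- rank(scores, ties.method = "average")
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired t-test across folds
#'
#' `t = mean(d) / (sd(d)/sqrt(n))` on the fold-wise differences
#' `d = a - b`, two-sided p with `n - 1` degrees of freedom. Degenerate
#' inputs are flagged: all-zero differences give `p = 1`; zero-variance
#' nonzero-mean differences give `p = 0`.
#'
#' @param scores_a,scores_b equal-length (>= 2) numeric vectors in the same
#'   fold order.
#' @return list with `t`, `df`, `p_value`, `mean_diff`, `flag`.
#' @export
paired_t_test <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    nn_stop("evaluation_error", "score vectors differ in length")
  if (length(scores_a) < 2)
    nn_stop("evaluation_error", "need >= 2 paired scores")
  d <- scores_a - scores_b
  n <- length(d)
  if (all(d == 0))
    return(list(t = 0, df = n - 1, p_value = 1, mean_diff = 0,
                flag = "degenerate: identical scores"))
  s <- sd(d)
  if (s == 0)
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p_value = 0,
                mean_diff = mean(d),
                flag = "degenerate: zero-variance nonzero differences"))
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1, p_value = 2 * pt(-abs(t), n - 1),
       mean_diff = mean(d), flag = NA_character_)
}

# Mean, sd (n-1 denominator) and t-based 95% CI of fold scores.
fold_summary <- function(x, conf = 0.95) {
  n <- length(x)
  m <- mean(x)
  s <- sd(x)
  half <- qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n)
  list(mean = m, sd = s, ci_lower = m - half, ci_upper = m + half)
}
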