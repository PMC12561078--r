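# Metadata standardization. Parameters are fit on training subjects only and
# reused verbatim for validation/held-out data (no-leakage contract).

#' Fit a feature standardizer on training metadata
#'
#' Per-feature mean and population standard deviation (ddof = 0, matching
#' scikit-learn's StandardScaler: the two-point column `c(0, 2)` has mean 1
#' and sd 1). Transforming the training matrix with the fitted parameters
#' yields columns with mean 0 and sd 1.
#'
#' @param X numeric matrix, rows = training subjects, columns = features
#'   (column names kept).
#' @return `scaler_params`: list with `mean` and `sd` vectors.
#' @export
fit_standardizer <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2)
    nn_stop("protocol_error", "need >= 2 training subjects to fit a standardizer")
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2, mu)^2))
  if (any(sdv <= 0)) {
    bad <- colnames(X)[sdv <= 0] %||% which(sdv <= 0)
    nn_stop("protocol_error", "zero-variance feature(s): %s",
            paste(bad, collapse = ", "))
  }
  structure(list(mean = mu, sd = sdv), class = "scaler_params")
}

#' Apply a fitted standardizer
#'
#' @param X numeric matrix with the same columns the standardizer was fit on.
#' @param params a `scaler_params` from [fit_standardizer()].
#' @return standardized matrix `(X - mean) / sd`.
#' @export
apply_standardizer <- function(X, params) {
  X <- as.matrix(X)
  if (ncol(X) != length(params$mean))
    nn_stop("protocol_error", "standardizer fitted on %d features, got %d",
            length(params$mean), ncol(X))
  sweep(sweep(X, 2, params$mean), 2, params$sd, `/`)
}
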