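# Metadata-to-text encoding.
#
# A subject's selected metadata is serialized to a deterministic template
# string ("FAQ-Score: 12.0; Age: 74.5; ..."), tokenized, embedded, padded or
# truncated to a fixed sequence length L, and projected into the shared
# embedding space (T' = T W_T + b_T). The default encoder backend is a
# deterministic, download-free stand-in: word tokens get seeded hash
# embeddings; numeric tokens get sinusoidal value encodings so that nearby
# values share representation (hash embeddings of raw numerals would not
# generalize across unseen values). A pretrained contextual encoder can be
# plugged in as any function(texts) -> (L x H x B) array.

#' Serialize selected metadata fields to text
#'
#' Deterministic template over the selected features in ranking order, with
#' fixed one-decimal numeric rendering: `"FAQ-Score: 12.0; Age: 74.5"`.
#'
#' @param record named list (or one-row data.frame) of metadata values.
#' @param selected ordered character vector of feature names to include.
#' @return single string.
#' @export
serialize_metadata <- function(record, selected) {
  record <- as.list(record)
  missing <- setdiff(selected, names(record))
  if (length(missing))
    nn_stop("encoding_error", "unknown feature(s): %s",
            paste(missing, collapse = ", "))
  vals <- vapply(selected, function(f) sprintf("%.1f", as.numeric(record[[f]])), "")
  paste(sprintf("%s: %s", selected, vals), collapse = "; ")
}

tokenize_text <- function(text) {
  if (!nzchar(text))
    nn_stop("encoding_error", "cannot encode empty text")
  t <- tolower(text)
  t <- gsub("([:;])", " \\1 ", t)
  toks <- strsplit(trimws(t), "\\s+")[[1]]
  toks[nzchar(toks)]
}

# djb2 string hash, folded into a positive integer seed
hash_string <- function(s) {
  h <- 5381
  for (code in utf8ToInt(s)) h <- (h * 33 + code) %% 2147483647
  as.integer(h)
}

is_numeric_token <- function(tok) {
  grepl("^-?[0-9]+(\\.[0-9]+)?$", tok)
}

# Embedding of one token. Numeric tokens: sinusoidal features of the value
# at geometrically spaced frequencies (smooth in the value). Word tokens:
# unit-scaled Gaussian vector seeded from the token hash (deterministic,
# vocabulary-free).
token_embedding <- function(tok, H) {
  if (is_numeric_token(tok)) {
    v <- as.numeric(tok)
    k <- seq_len(ceiling(H / 2))
    freq <- 2.4^(-(k - 1) / 2)        # ~2.4 down to well below 1
    e <- as.vector(rbind(sin(v * freq), cos(v * freq)))
    e[seq_len(H)]
  } else {
    if (!exists(".Random.seed", envir = globalenv())) runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(hash_string(tok))
    rnorm(H)
  }
}

#' Deterministic stand-in text encoder
#'
#' Returns an encoder function mapping a character vector of `B` texts to a
#' `(L, H, B)` embedding array: each text is tokenized, each token embedded
#' (hash embedding for words, sinusoidal value encoding for numbers),
#' truncated to `L` tokens and padded with the zero pad embedding. Fully
#' deterministic and download-free.
#'
#' @param max_len sequence length `L` after pad/truncate.
#' @param hidden embedding width `H`.
#' @return function(texts) -> `(L, H, B)` array with attributes used by
#'   [encode_text()].
#' @export
hash_text_encoder <- function(max_len = 256, hidden = 64) {
  cache <- new.env(parent = emptyenv())
  force(max_len); force(hidden)
  function(texts) {
    B <- length(texts)
    out <- array(0, c(max_len, hidden, B))
    for (b in seq_len(B)) {
      toks <- tokenize_text(texts[b])
      n <- min(length(toks), max_len)
      for (i in seq_len(n)) {
        tk <- toks[i]
        key <- paste0("t:", tk)
        if (is.null(cache[[key]])) cache[[key]] <- token_embedding(tk, hidden)
        out[i, , b] <- cache[[key]]
      }
    }
    out
  }
}

#' Encode a batch of metadata texts
#'
#' @param texts character vector (one serialized record per batch item).
#' @param encoder an encoder backend: a function(texts) returning a
#'   `(L, H, B)` array, e.g. [hash_text_encoder()]. Any pretrained contextual
#'   encoder with the same signature can be plugged in.
#' @return `(L, H, B)` numeric array of token embeddings.
#' @export
encode_text <- function(texts, encoder = hash_text_encoder()) {
  if (any(!nzchar(texts)))
    nn_stop("encoding_error", "cannot encode empty text")
  T <- encoder(texts)
  if (length(dim(T)) != 3 || dim(T)[3] != length(texts))
    nn_stop("encoding_error", "encoder must return an (L, H, B) array")
  if (any(!is.finite(T)))
    nn_stop("encoding_error", "encoder produced non-finite embeddings")
  T
}

#' Project text embeddings into the shared space
#'
#' Applies `T' = T W_T + b_T` independently at every token position.
#'
#' @param T `(L, H, B)` embedding array.
#' @param W_T `(H x E)` projection matrix.
#' @param b_T length-`E` bias.
#' @return `(L, E, B)` array.
#' @export
project_text <- function(T, W_T, b_T = NULL) {
  d <- dim(T)
  if (ncol(as.matrix(W_T)) < 1 || d[2] != nrow(W_T))
    nn_stop("encoding_error", "W_T expects hidden size %d, got %d",
            d[2], nrow(W_T))
  E <- ncol(W_T)
  b_T <- b_T %||% numeric(E)
  out <- array(0, c(d[1], E, d[3]))
  for (b in seq_len(d[3]))
    out[, , b] <- sweep(matrix(T[, , b], d[1], d[2]) %*% W_T, 2, b_T, `+`)
  out
}

# Serialize the metadata for every subject of a batch; `records` is a list of
# named lists already standardized and restricted upstream. When
# use_text_encoder is off, records bypass serialization and each selected
# value becomes one numeric token (value encoding only).
metadata_texts <- function(records, selected) {
  vapply(records, serialize_metadata, "", selected = selected)
}

numeric_token_texts <- function(records, selected) {
  vapply(records, function(r)
    paste(sprintf("%.1f", as.numeric(as.list(r)[selected])), collapse = " "),
    "")
}
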