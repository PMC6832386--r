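#' @include walks.R
NULL

#' Train Skip-gram embeddings on a walk corpus
#'
#' Learns one d-dimensional vector per drug appearing in the corpus by
#' maximizing the likelihood of each node's walk-context under the
#' Skip-gram model, estimated with negative sampling (unigram^0.75 noise
#' distribution) and single-threaded SGD with a linearly decaying learning
#' rate.  Context windows never cross walk boundaries; length-1 walks
#' contribute only to the vocabulary.  Training is bitwise reproducible
#' for a fixed seed.
#'
#' @param corpus a [WalkCorpus-class].
#' @param dim embedding dimension d (default 32).
#' @param window symmetric context window size (default 5).
#' @param epochs SGD passes over the corpus (default 5).
#' @param negative negative samples per context pair (default 5).
#' @param lr initial learning rate (default 0.025), decayed linearly to
#'   near zero over training.
#' @param seed integer seed for initialization and noise sampling.
#' @return An [EmbeddingSet-class]; `meta` records the hyperparameters and
#'   the per-epoch average loss (`lossByEpoch`, nats per context pair).
#' @export
trainSkipgram <- function(corpus, dim = 32, window = 5, epochs = 5,
                          negative = 5, lr = 0.025, seed = 1L) {
  stopifnot(is(corpus, "WalkCorpus"), dim >= 1, window >= 1, epochs >= 1,
            negative >= 0, lr > 0)
  w <- walks(corpus)
  if (!length(w)) stop("corpus is empty")
  vocab <- sort(unique(unlist(w, use.names = FALSE)))
  if (length(vocab) < negative + 1L)
    stop(sprintf("vocabulary (%d) must exceed the negative sample count (%d)",
                 length(vocab), negative))
  coded <- lapply(w, function(x) match(x, vocab) - 1L)
  fit <- cpp_train_skipgram(coded, length(vocab), as.integer(dim),
                            as.integer(window), as.integer(epochs),
                            as.integer(negative), lr, as.integer(seed))
  vec <- fit$vectors
  rownames(vec) <- vocab
  EmbeddingSet(vec, meta = list(window = as.integer(window),
                                epochs = as.integer(epochs),
                                negative = as.integer(negative),
                                lr = lr, seed = as.integer(seed),
                                lossByEpoch = as.numeric(fit$lossByEpoch),
                                finalLoss = as.numeric(
                                  fit$lossByEpoch[length(fit$lossByEpoch)])))
}

#' Write embeddings in word2vec text format
#'
#' Header line `"<V> <d>"`, then one line per drug: the id followed by d
#' space-separated coordinates printed with six decimals.
#'
#' @param E an [EmbeddingSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEmbeddings <- function(E, path) {
  stopifnot(is(E, "EmbeddingSet"))
  v <- embeddingMatrix(E)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(v), ncol(v)), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(rownames(v)[i],
                     paste(sprintf("%.6f", v[i, ]), collapse = " ")), con)
  invisible(path)
}

#' Read embeddings from word2vec text format
#'
#' @param path file written by [writeEmbeddings()] (or any word2vec text
#'   file).
#' @return An [EmbeddingSet-class].
#' @export
readEmbeddings <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty embedding file")
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  if (length(hdr) != 2L || anyNA(hdr))
    stop("malformed header line (expected '<V> <d>')")
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr[1L])
    stop(sprintf("header declares %d vectors but file has %d",
                 hdr[1L], length(body)))
  parts <- strsplit(trimws(body), "\\s+")
  if (any(lengths(parts) != hdr[2L] + 1L))
    stop("vector length does not match header dimension")
  ids <- vapply(parts, `[[`, character(1), 1L)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                  numeric(hdr[2L])))
  if (hdr[2L] == 1L) vec <- matrix(vec, ncol = 1L)
  rownames(vec) <- ids
  EmbeddingSet(vec)
}
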