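#' Pretrain word embeddings from a corpus
#'
#' Builds distributional word vectors from sentence-internal co-occurrence
#' counts: a symmetric window is slid over every tokenized sentence, the
#' positive pointwise mutual information (PPMI) matrix is formed, and its
#' truncated SVD gives `dim`-dimensional vectors (rows scaled by the square
#' root of the singular values). Tokens sharing contexts end up close in
#' cosine similarity. A reserved `<unk>` row — the mean of all word vectors —
#' handles out-of-vocabulary tokens downstream.
#'
#' The factorization is deterministic (sign-fixed SVD), so the same corpus
#' always yields the same table.
#'
#' @param corpus a labeled-corpus tibble (column `text`), or a character
#'   vector of sentences.
#' @param dim embedding width; default 50.
#' @param seed integer, kept for interface symmetry with the stochastic
#'   trainers this pipeline may plug in; the count-based trainer is already
#'   deterministic.
#' @param window symmetric context window in tokens; default 2.
#' @return numeric matrix, one row per vocabulary token plus the final
#'   `<unk>` row; rownames are tokens.
#' @export
pretrain_embeddings <- function(corpus, dim = 50, seed = 1L, window = 2L) {
  if (!is_count(dim)) abort("`dim` must be a positive integer")
  sentences <- if (is.data.frame(corpus)) corpus$text else as.character(corpus)
  if (length(sentences) == 0L) abort("`corpus` is empty")
  toks <- lapply(sentences, tokenize)
  vocab <- sort(unique(unlist(toks)))
  if (length(vocab) == 0L) abort("`corpus` has no tokens")
  v <- length(vocab)

  # sentence-bounded symmetric-window co-occurrence counts
  ii <- integer(0); jj <- integer(0)
  for (s in toks) {
    idx <- match(s, vocab)
    n <- length(idx)
    if (n < 2L) next
    for (off in seq_len(min(window, n - 1L))) {
      a <- idx[seq_len(n - off)]
      b <- idx[seq.int(off + 1L, n)]
      ii <- c(ii, a, b); jj <- c(jj, b, a)
    }
  }
  co <- as.matrix(Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(v, v)))

  total <- sum(co)
  if (total == 0) {
    emb <- matrix(0, v, dim)
  } else {
    pw <- rowSums(co) / total
    pc <- colSums(co) / total
    pmi <- log(pmax(co / total, .Machine$double.xmin) / outer(pw, pc))
    pmi[co == 0] <- 0
    ppmi <- pmax(pmi, 0)
    k <- min(dim, v)
    sv <- svd(ppmi, nu = k, nv = 0)
    u <- sv$u
    # fix the sign of each singular vector so the decomposition is unique
    for (j in seq_len(ncol(u))) {
      piv <- which.max(abs(u[, j]))
      if (u[piv, j] < 0) u[, j] <- -u[, j]
    }
    emb <- u %*% diag(sqrt(sv$d[seq_len(k)]), k)
    if (k < dim) emb <- cbind(emb, matrix(0, v, dim - k))
  }
  emb <- rbind(emb, colMeans(emb))
  rownames(emb) <- c(vocab, "<unk>")
  emb
}
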