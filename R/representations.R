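#' Dense document-vector representations
#'
#' Internal constructor for the common container holding reduced document
#' vectors of one of the three kinds: `svd` (latent semantic scores),
#' `topic` (LDA topic proportions), `embedding` (frequency-weighted average
#' word vectors).
#'
#' @param matrix Numeric matrix, documents x dims, rownames = doc ids.
#' @param kind `"svd"`, `"topic"` or `"embedding"`.
#' @param flagged Character vector of doc ids excluded from distance
#'   computations (zero vectors / no in-vocabulary words).
#' @return A `doc_vectors` object.
#' @keywords internal
doc_vectors <- function(matrix, kind, flagged = character()) {
  stopifnot(kind %in% c("svd", "topic", "embedding"))
  structure(
    list(matrix = matrix, doc_ids = rownames(matrix), kind = kind,
         dims = ncol(matrix), flagged = flagged),
    class = "doc_vectors"
  )
}

#' @export
print.doc_vectors <- function(x, ...) {
  cat(sprintf("<doc_vectors:%s> %d documents x %d dims", x$kind,
              nrow(x$matrix), x$dims))
  if (length(x$flagged)) cat(sprintf(" (%d flagged)", length(x$flagged)))
  cat("\n")
  invisible(x)
}

#' Latent semantic document vectors by truncated SVD
#'
#' Computes document scores on the top-`d` left singular directions of the
#' count matrix, scaled by the singular values (rows of U * Sigma), which
#' preserves the inner-product geometry of the raw counts. The truncated
#' factorization is obtained from a symmetric eigendecomposition of the
#' document Gram matrix, so only the documents-x-documents problem is ever
#' densified.
#'
#' @param dfm A `dfm` (typically the n-gram matrix after
#'   [select_common_features()]).
#' @param d Number of dimensions to keep (>= 1). If the matrix rank `r` is
#'   smaller, `d` is reduced to `r` with a warning.
#' @return `doc_vectors` of kind `"svd"`. All-zero documents are flagged.
#' @export
svd_reduce <- function(dfm, d) {
  stopifnot(inherits(dfm, "dfm"), d >= 1)
  X <- dfm$matrix
  G <- as.matrix(Matrix::tcrossprod(X))
  eg <- eigen(G, symmetric = TRUE)
  tol <- max(eg$values[1], 0) * max(dim(X)) * .Machine$double.eps
  r <- sum(eg$values > max(tol, 0))
  if (r == 0L) stop("document-feature matrix has rank 0")
  if (d > r) {
    warning("requested d = ", d, " exceeds matrix rank ", r,
            "; returning ", r, " dimensions")
    d <- r
  }
  sv <- sqrt(eg$values[seq_len(d)])
  U <- eg$vectors[, seq_len(d), drop = FALSE]
  # deterministic sign convention: largest-magnitude loading positive
  for (j in seq_len(d)) {
    pk <- which.max(abs(U[, j]))
    if (U[pk, j] < 0) U[, j] <- -U[, j]
  }
  scores <- U * rep(sv, each = nrow(U))
  rownames(scores) <- dfm$doc_ids
  colnames(scores) <- paste0("sv", seq_len(d))
  zero <- dfm$doc_ids[Matrix::rowSums(X) == 0]
  doc_vectors(scores, "svd", flagged = zero)
}

#' Topic-proportion document vectors by latent Dirichlet allocation
#'
#' Fits LDA with a collapsed Gibbs sampler (symmetric document-topic prior
#' `alpha = 1/T`, topic-word prior `beta = 0.01`) and returns the posterior
#' mean topic distribution per document. Documents with an empty stream get
#' the uniform distribution and are flagged.
#'
#' @param dfm A `dfm`, conventionally built from the nouns-and-verbs stream.
#' @param T Number of topics (>= 1; must not exceed the vocabulary size).
#' @param seed Integer RNG seed; the fit is reproducible for a fixed seed.
#' @param n_iter Gibbs sweeps (default 500).
#' @param alpha,beta Dirichlet hyper-parameters; `alpha = NULL` means `1/T`.
#' @return `doc_vectors` of kind `"topic"`; every row sums to 1.
#' @export
fit_topics <- function(dfm, T, seed, n_iter = 500, alpha = NULL,
                       beta = 0.01) {
  stopifnot(inherits(dfm, "dfm"), T >= 1)
  V <- ncol(dfm$matrix)
  if (T > V) {
    stop("number of topics T = ", T, " exceeds vocabulary size ", V)
  }
  if (is.null(alpha)) alpha <- 1 / T
  if (T == 1L) {
    theta <- matrix(1, nrow(dfm$matrix), 1,
                    dimnames = list(dfm$doc_ids, "topic1"))
    return(doc_vectors(theta, "topic"))
  }
  tm <- methods::as(dfm$matrix, "TsparseMatrix")
  # expand to one entry per token occurrence
  doc_id <- rep.int(tm@i, as.integer(round(tm@x)))
  word_id <- rep.int(tm@j, as.integer(round(tm@x)))
  o <- order(doc_id, word_id)
  theta <- lda_gibbs_cpp(doc_id[o], word_id[o], nrow(dfm$matrix), V,
                         as.integer(T), alpha, beta, as.integer(n_iter),
                         as.integer(seed %% .Machine$integer.max))
  rownames(theta) <- dfm$doc_ids
  colnames(theta) <- paste0("topic", seq_len(T))
  empty <- dfm$doc_ids[Matrix::rowSums(dfm$matrix) == 0]
  if (length(empty)) {
    theta[empty, ] <- 1 / T
    warning(length(empty), " empty document(s) assigned the uniform topic ",
            "distribution and flagged")
  }
  doc_vectors(theta, "topic", flagged = empty)
}

#' Frequency-weighted average word-embedding document vectors
#'
#' Each document is represented as the average of its in-vocabulary word
#' vectors weighted by frequency count:
#' `row_i = sum_w count_iw * v_w / sum_w count_iw`. Out-of-vocabulary
#' features are dropped; documents with no in-vocabulary word are flagged
#' (and excluded from embedding-based distances).
#'
#' @param dfm A `dfm`, conventionally built from the words stream.
#' @param wv A `word_vectors` object from [load_word_vectors()] or
#'   [train_toy_embeddings()].
#' @return `doc_vectors` of kind `"embedding"`.
#' @export
embed_docs <- function(dfm, wv) {
  stopifnot(inherits(dfm, "dfm"), inherits(wv, "word_vectors"))
  iv <- dfm$features %in% rownames(wv$vectors)
  if (!any(iv)) stop("no document has an in-vocabulary word")
  X <- dfm$matrix[, iv, drop = FALSE]
  V <- wv$vectors[colnames(X), , drop = FALSE]
  tot <- Matrix::rowSums(X)
  E <- as.matrix(X %*% V)
  nz <- tot > 0
  E[nz, ] <- E[nz, , drop = FALSE] / tot[nz]
  rownames(E) <- dfm$doc_ids
  flagged <- dfm$doc_ids[!nz]
  if (length(flagged)) {
    warning(length(flagged), " document(s) have no in-vocabulary words; ",
            "flagged and excluded from embedding distances")
  }
  doc_vectors(E, "embedding", flagged = flagged)
}

#' Read word vectors in plain "word v1 ... vD" text format
#'
#' One word per line followed by whitespace-separated floats; all lines must
#' have the same dimension. Duplicate words resolve last-wins with a
#' warning.
#'
#' @param path File path.
#' @return A `word_vectors` object: list with `vectors` (matrix, rownames =
#'   words) and `dims`.
#' @export
load_word_vectors <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty word-vector file: ", path)
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  dims <- lengths(parts) - 1L
  if (any(dims < 1L)) {
    stop("word-vector format error at line ", which(dims < 1L)[1],
         ": no vector components")
  }
  if (length(unique(dims)) > 1L) {
    bad <- which(dims != dims[1])[1]
    stop("word-vector format error at line ", bad, ": expected ", dims[1],
         " dims, found ", dims[bad])
  }
  words <- vapply(parts, `[[`, "", 1L)
  vals <- vapply(parts, function(p) as.numeric(p[-1]), numeric(dims[1]))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(rbind(vals)), 2, any))[1]
    stop("word-vector format error at line ", bad, ": non-numeric component")
  }
  m <- if (dims[1] == 1L) matrix(vals, ncol = 1L) else t(vals)
  rownames(m) <- words
  if (anyDuplicated(words)) {
    warning("duplicate word(s) in vector file; keeping the last occurrence")
    keep <- !duplicated(words, fromLast = TRUE)
    m <- m[keep, , drop = FALSE]
  }
  structure(list(vectors = m, dims = ncol(m)), class = "word_vectors")
}

#' @rdname load_word_vectors
#' @param wv A `word_vectors` object.
#' @return For `write_word_vectors()`: `path`, invisibly.
#' @export
write_word_vectors <- function(wv, path) {
  stopifnot(inherits(wv, "word_vectors"))
  lines <- paste(
    rownames(wv$vectors),
    apply(wv$vectors, 1, function(v)
      paste(formatC(v, format = "g", digits = 17), collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.word_vectors <- function(x, ...) {
  cat(sprintf("<word_vectors> %d words x %d dims\n", nrow(x$vectors),
              x$dims))
  invisible(x)
}
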