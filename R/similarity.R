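#' Cosine distance between document vectors
#'
#' Distance is `1 - cos(u, v)`: 0 for identical directions, 1 for
#' orthogonal vectors, up to 2 for signed vectors.
#'
#' @param u,v Numeric vectors of equal length, both non-zero.
#' @return A single distance.
#' @export
cosine_distance <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine distance undefined for a zero vector")
  }
  1 - sum(u * v) / (nu * nv)
}

#' Full pairwise cosine-distance matrix
#'
#' @param X Numeric matrix, documents in rows. Zero rows raise an error
#'   (flagged documents must be excluded by the caller).
#' @return Symmetric matrix of `1 - cosine` distances with zero diagonal.
#' @export
cosine_distance_matrix <- function(X) {
  nr <- sqrt(rowSums(X^2))
  if (any(nr == 0)) {
    stop("cosine distance undefined for zero row(s): ",
         paste(utils::head(which(nr == 0)), collapse = ", "))
  }
  Xn <- X / nr
  D <- 1 - tcrossprod(Xn)
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

#' Word-mover distance between two documents
#'
#' Exact earth-mover distance between the normalized word-frequency
#' distributions of the two documents, with ground cost the cosine distance
#' between word vectors; solved by a transportation simplex. A relaxed
#' lower-bound mode (`exact = FALSE`) replaces the transport problem by the
#' larger of its two row/column relaxations — cheaper, and always a lower
#' bound on the exact distance.
#'
#' @param bow_a,bow_b Named numeric vectors of word counts (names = words).
#' @param wv A `word_vectors` object.
#' @param exact Logical; exact transport (default) or relaxed lower bound.
#' @return A single distance (>= 0).
#' @export
wmd_distance <- function(bow_a, bow_b, wv, exact = TRUE) {
  stopifnot(inherits(wv, "word_vectors"))
  emb <- wmd_norm_emb(wv)
  pa <- wmd_prep(bow_a, rownames(emb))
  pb <- wmd_prep(bow_b, rownames(emb))
  if (exact) {
    wmd_pair_cpp(pa$idx, pa$w, pb$idx, pb$w, emb)
  } else {
    relaxed_wmd(pa, pb, emb)
  }
}

# L2-normalize embedding rows once (cached on the object via an attribute
# would mutate; providers cache instead)
wmd_norm_emb <- function(wv) {
  m <- wv$vectors
  nr <- sqrt(rowSums(m^2))
  if (any(nr == 0)) {
    m <- m[nr > 0, , drop = FALSE]
    nr <- nr[nr > 0]
  }
  m / nr
}

# counts -> (0-based vocab indices, normalized weights)
wmd_prep <- function(bow, vocab) {
  bow <- bow[bow > 0]
  idx <- match(names(bow), vocab)
  keep <- !is.na(idx)
  if (!any(keep)) {
    stop("word-mover distance undefined: no in-vocabulary words")
  }
  w <- as.numeric(bow[keep])
  list(idx = as.integer(idx[keep]) - 1L, w = w / sum(w))
}

relaxed_wmd <- function(pa, pb, emb) {
  C <- 1 - emb[pa$idx + 1L, , drop = FALSE] %*%
    t(emb[pb$idx + 1L, , drop = FALSE])
  C[C < 0] <- 0
  max(sum(pa$w * apply(C, 1, min)), sum(pb$w * apply(C, 2, min)))
}

#' Distance providers
#'
#' A distance provider answers k-nearest-neighbour queries for one document
#' representation. `vector_provider()` serves cosine distances over rows of
#' a `doc_vectors` object (`svd_cosine` / `topic_cosine` kinds);
#' `wmd_provider()` serves word-mover distances over bag-of-words documents.
#' Distances from each queried document to the whole corpus are computed on
#' first use and cached, so repeated queries (and larger `k`) are cheap.
#'
#' @param vectors A `doc_vectors` object (kind `svd` or `topic`).
#' @return A `distance_provider`: list with `kind`, `doc_ids`, and
#'   `query(doc_id, k)` returning a data.frame of `id`, `distance` ordered
#'   by ascending distance with ties broken by ascending id, never
#'   containing the query document or flagged documents.
#' @export
vector_provider <- function(vectors) {
  stopifnot(inherits(vectors, "doc_vectors"))
  kind <- paste0(if (vectors$kind == "topic") "topic" else "svd", "_cosine")
  ids <- vectors$doc_ids
  ok <- setdiff(ids, vectors$flagged)
  X <- vectors$matrix[ok, , drop = FALSE]
  nr <- sqrt(rowSums(X^2))
  Xn <- X / pmax(nr, .Machine$double.xmin)
  cache <- new.env(parent = emptyenv())
  query <- function(doc_id, k) {
    d <- cache[[doc_id]]
    if (is.null(d)) {
      i <- match(doc_id, ok)
      if (is.na(i)) stop("unknown or flagged doc id: ", doc_id)
      d <- 1 - as.numeric(Xn %*% Xn[i, ])
      d[d < 0] <- 0
      names(d) <- ok
      cache[[doc_id]] <- d
    }
    provider_topk(d, doc_id, k)
  }
  structure(list(kind = kind, doc_ids = ok, query = query),
            class = "distance_provider")
}

provider_topk <- function(d, doc_id, k) {
  d <- d[names(d) != doc_id]
  o <- order(d, names(d), method = "radix")
  o <- o[seq_len(min(k, length(o)))]
  data.frame(id = names(d)[o], distance = unname(d[o]),
             stringsAsFactors = FALSE)
}

#' @rdname vector_provider
#' @param dfm A `dfm` over the words stream (bag-of-words per document).
#' @param wv A `word_vectors` object.
#' @param cap Per-document cap on distinct words entering the transport
#'   problem: when a document has more, only its `cap` most frequent
#'   in-vocabulary words are used (ties by word, re-normalized). `Inf`
#'   disables capping.
#' @param exact Exact transport (default) or relaxed lower-bound mode.
#' @export
wmd_provider <- function(dfm, wv, cap = 50, exact = TRUE) {
  stopifnot(inherits(dfm, "dfm"), inherits(wv, "word_vectors"))
  emb <- wmd_norm_emb(wv)
  vocab <- rownames(emb)
  tm <- methods::as(dfm$matrix, "TsparseMatrix")
  col_ok <- dfm$features %in% vocab
  keep <- col_ok[tm@j + 1L]
  di <- tm@i[keep] + 1L
  wi <- match(dfm$features[tm@j[keep] + 1L], vocab)
  xx <- tm@x[keep]
  docs_idx <- vector("list", length(dfm$doc_ids))
  docs_w <- vector("list", length(dfm$doc_ids))
  for (d in seq_along(docs_idx)) {
    docs_idx[[d]] <- integer()
    docs_w[[d]] <- numeric()
  }
  sp <- split(seq_along(di), di)
  for (nm in names(sp)) {
    rows <- sp[[nm]]
    idx <- wi[rows]; w <- xx[rows]
    if (is.finite(cap) && length(idx) > cap) {
      o <- order(-w, vocab[idx], method = "radix")[seq_len(cap)]
      idx <- idx[o]; w <- w[o]
    }
    d <- as.integer(nm)
    docs_idx[[d]] <- as.integer(idx - 1L)
    docs_w[[d]] <- w / sum(w)
  }
  ids <- dfm$doc_ids
  empty <- lengths(docs_idx) == 0L
  ok <- ids[!empty]
  idx_ok <- docs_idx[!empty]
  w_ok <- docs_w[!empty]
  cache <- new.env(parent = emptyenv())
  query <- function(doc_id, k) {
    i <- match(doc_id, ok)
    if (is.na(i)) stop("unknown or flagged doc id: ", doc_id)
    if (!exact) {
      d <- cache[[doc_id]]
      if (is.null(d)) {
        d <- as.numeric(rwmd_one_vs_many_cpp(idx_ok[[i]], w_ok[[i]],
                                             idx_ok, w_ok, emb))
        names(d) <- ok
        cache[[doc_id]] <- d
      }
      return(provider_topk(d, doc_id, k))
    }
    hit <- cache[[doc_id]]
    if (is.null(hit) || hit$k_certified < k) {
      # exact transport solved only where the relaxed lower bound cannot
      # exclude a document from the top k (prefetch-and-prune); certify a
      # little deeper than asked so later queries at a larger k (e.g. the
      # phase-2 neighbour count) hit the cache
      kc <- max(k, 16L)
      res <- wmd_knn_cpp(idx_ok[[i]], w_ok[[i]], idx_ok, w_ok, emb,
                         i - 1L, as.integer(kc))
      hit <- list(dist = stats::setNames(as.numeric(res$dist), ok),
                  solved = as.logical(res$solved), k_certified = kc)
      cache[[doc_id]] <- hit
    }
    d <- hit$dist[hit$solved]
    provider_topk(d, doc_id, k)
  }
  structure(list(kind = if (exact) "wmd" else "wmd_relaxed",
                 doc_ids = ok, query = query),
            class = "distance_provider")
}

#' @export
print.distance_provider <- function(x, ...) {
  cat(sprintf("<distance_provider:%s> %d documents\n", x$kind,
              length(x$doc_ids)))
  invisible(x)
}

#' k-nearest-neighbour expansion from eligible seed documents
#'
#' Takes the union, over every seed and every distance provider, of the `k`
#' nearest neighbours, then removes the seeds themselves and anything
#' already screened. With `s` seeds and `p` providers the result has at
#' most `s * k * p` documents (duplications removed). Ties are broken by
#' ascending document id, so runs are bit-reproducible.
#'
#' @param seeds Character vector of eligible doc ids (non-empty).
#' @param k Neighbours per seed per provider (>= 1).
#' @param providers List of `distance_provider` objects.
#' @param already_screened Character vector of doc ids to exclude.
#' @return Character vector of candidate doc ids, sorted.
#' @export
knn_expand <- function(seeds, k, providers, already_screened = character()) {
  stopifnot(length(seeds) > 0, k >= 1)
  if (inherits(providers, "distance_provider")) providers <- list(providers)
  out <- character()
  for (prov in providers) {
    for (s in seeds) {
      if (!(s %in% prov$doc_ids)) next
      out <- c(out, prov$query(s, k)$id)
    }
  }
  sort_c(setdiff(unique(out), c(seeds, already_screened)))
}
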