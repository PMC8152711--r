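#' Synthetic screening-corpus configuration
#'
#' Parameters of the generative topic model used to simulate a citation
#' corpus with the statistical structure the screening workflow assumes: a
#' large majority of ineligible documents, a small semantically clustered
#' eligible class (low prevalence), and a handful of known-eligible seed
#' documents.
#'
#' @param n_docs Number of citations (default 2000).
#' @param prevalence Eligible fraction in (0, 1) (default 0.05); the
#'   eligible count is exactly `floor(prevalence * n_docs)` by
#'   construction.
#' @param n_topics Number of latent topics (default 30).
#' @param eligible_topic_ids Topics that characterize eligible documents
#'   (default `1:3`); must be a non-empty proper subset of the topics.
#' @param vocab_size Vocabulary size (default 500); words are synthetic
#'   strings `w0001`, `w0002`, ... with POS tags assigned cyclically over
#'   `NOUN, VERB, ADJ, ADV, OTHER` so the nouns/verbs stream is
#'   non-trivial.
#' @param doc_length_mean Mean document length in words, Poisson
#'   distributed with a floor of 20 (default 150).
#' @param eligible_mixture_boost Factor (>= 1) multiplying the Dirichlet
#'   weight of the eligible topics in eligible documents (default 5).
#' @param n_seeds Number of eligible documents flagged as seeds
#'   (default 3; 3-5 typical).
#' @param alpha Base document-topic Dirichlet concentration (default 0.5).
#' @param beta Topic-word Dirichlet concentration (default 0.05; sparse
#'   topical vocabularies).
#' @param seed Integer RNG seed; generation is fully reproducible.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_docs = 2000, prevalence = 0.05, n_topics = 30,
                         eligible_topic_ids = 1:3, vocab_size = 500,
                         doc_length_mean = 150,
                         eligible_mixture_boost = 5, n_seeds = 3,
                         alpha = 0.5, beta = 0.05, seed = 1) {
  stopifnot(prevalence > 0, prevalence < 1, doc_length_mean > 0,
            eligible_mixture_boost >= 1, n_topics >= 2,
            length(eligible_topic_ids) >= 1,
            all(eligible_topic_ids %in% seq_len(n_topics)),
            length(eligible_topic_ids) < n_topics,
            n_seeds >= 1)
  n_eligible <- floor(prevalence * n_docs)
  if (n_eligible < n_seeds) {
    stop("prevalence * n_docs = ", n_eligible,
         " is smaller than the requested ", n_seeds, " seed documents")
  }
  structure(list(
    n_docs = as.integer(n_docs), prevalence = prevalence,
    n_topics = as.integer(n_topics),
    eligible_topic_ids = as.integer(eligible_topic_ids),
    vocab_size = as.integer(vocab_size),
    doc_length_mean = doc_length_mean,
    eligible_mixture_boost = eligible_mixture_boost,
    n_seeds = as.integer(n_seeds), alpha = alpha, beta = beta,
    seed = as.integer(seed)
  ), class = "synth_config")
}

rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate a labelled synthetic screening corpus
#'
#' Topic-word distributions are drawn from a sparse symmetric Dirichlet;
#' each document draws a topic mixture (eligible documents multiply the
#' Dirichlet weight of the eligible topics by `eligible_mixture_boost`)
#' and a Poisson word count, then samples word tokens topic by topic.
#' Eligibility labels are assigned by construction — exactly
#' `floor(prevalence * n_docs)` documents are generated from the
#' eligible mixture — and shuffled into a seeded random document order.
#'
#' @param cfg A [synth_config()].
#' @return A `screen_corpus` with a `label` column and attributes:
#'   `seeds` (ids of the designated known-eligible seed documents),
#'   `pos_lexicon` (word -> coarse POS tag), `theta` (true topic mixtures,
#'   documents x topics), `synth_config`.
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  V <- cfg$vocab_size
  K <- cfg$n_topics
  vocab <- sprintf("w%04d", seq_len(V))
  tags <- c("NOUN", "VERB", "ADJ", "ADV", "OTHER")
  pos_lexicon <- stats::setNames(tags[(seq_len(V) - 1L) %% 5L + 1L], vocab)

  phi <- t(vapply(seq_len(K),
                  function(k) rdirichlet_one(rep(cfg$beta, V)),
                  numeric(V)))  # K x V topic-word distributions

  n <- cfg$n_docs
  n_elig <- floor(cfg$prevalence * n)
  labels <- sample(c(rep(1L, n_elig), rep(0L, n - n_elig)))

  base_alpha <- rep(cfg$alpha, K)
  elig_alpha <- base_alpha
  elig_alpha[cfg$eligible_topic_ids] <-
    cfg$alpha * cfg$eligible_mixture_boost

  theta <- matrix(0, n, K)
  docs <- vector("list", n)
  lens <- pmax(20L, stats::rpois(n, cfg$doc_length_mean))
  for (d in seq_len(n)) {
    a <- if (labels[d] == 1L) elig_alpha else base_alpha
    th <- rdirichlet_one(a)
    theta[d, ] <- th
    z <- sample.int(K, lens[d], replace = TRUE, prob = th)
    w <- vapply(z, function(k) sample.int(V, 1L, prob = phi[k, ]), 1L)
    docs[[d]] <- vocab[w]
  }

  ids <- sprintf("doc%05d", seq_len(n))
  titles <- vapply(docs, function(w)
    paste(w[seq_len(min(8L, length(w)))], collapse = " "), "")
  abstracts <- vapply(docs, function(w) {
    w <- w[-seq_len(min(8L, length(w)))]
    if (!length(w)) w <- "wpad"
    sent <- split(w, ceiling(seq_along(w) / 12))
    paste0(paste(vapply(sent, paste, "", collapse = " "), collapse = ". "),
           ".")
  }, "")

  corpus <- as_corpus(data.frame(id = ids, title = titles,
                                 abstract = abstracts, label = labels,
                                 stringsAsFactors = FALSE))
  seeds <- sample(ids[labels == 1L], cfg$n_seeds)
  rownames(theta) <- ids
  attr(corpus, "seeds") <- sort(seeds)
  attr(corpus, "pos_lexicon") <- pos_lexicon
  attr(corpus, "theta") <- theta
  attr(corpus, "synth_config") <- cfg
  corpus
}

#' Train small word embeddings from a corpus
#'
#' Builds a symmetric word co-occurrence matrix (window of 5 tokens over
#' the screening texts), applies positive pointwise mutual information
#' (PPMI) weighting, and takes a truncated SVD; word vectors are rows of
#' `U * sqrt(Sigma)`. Every in-corpus word gets a vector: words with an
#' all-zero PPMI row fall back to a small seeded Gaussian vector (and are
#' reported). These toy embeddings give the synthetic pipeline a
#' self-contained stand-in for large pretrained vector sets.
#'
#' @param corpus A `screen_corpus`.
#' @param D Embedding dimension (>= 2); reduced with a warning if the PPMI
#'   matrix rank is lower.
#' @param seed Integer seed (fallback vectors and reproducibility).
#' @param window Co-occurrence window size (default 5).
#' @return A `word_vectors` object covering all in-corpus words.
#' @export
train_toy_embeddings <- function(corpus, D, seed, window = 5) {
  stopifnot(inherits(corpus, "screen_corpus"), nrow(corpus) > 0, D >= 2)
  texts <- screening_texts(corpus)
  toks <- lapply(texts, function(tx) {
    tolower(regmatches(tx, gregexpr("[[:alnum:]][[:alnum:]'-]*", tx))[[1]])
  })
  vocab <- sort_c(unique(unlist(toks, use.names = FALSE)))
  nv <- length(vocab)
  ii <- list(); jj <- list()
  for (tk in toks) {
    x <- match(tk, vocab)
    L <- length(x)
    for (off in seq_len(min(window, L - 1))) {
      ii[[length(ii) + 1L]] <- x[seq_len(L - off)]
      jj[[length(jj) + 1L]] <- x[seq_len(L - off) + off]
    }
  }
  i <- unlist(ii, use.names = FALSE)
  j <- unlist(jj, use.names = FALSE)
  C <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(nv, nv))
  tot <- sum(C@x)
  rs <- Matrix::rowSums(C)
  Ct <- methods::as(C, "TsparseMatrix")
  pmi <- log((Ct@x / tot) / (rs[Ct@i + 1L] / tot * rs[Ct@j + 1L] / tot))
  keep <- pmi > 0
  P <- Matrix::sparseMatrix(i = Ct@i[keep] + 1L, j = Ct@j[keep] + 1L,
                            x = pmi[keep], dims = c(nv, nv))
  Pd <- as.matrix(P)
  sv <- svd(Pd)
  r <- sum(sv$d > sv$d[1] * nv * .Machine$double.eps)
  if (D > r) {
    warning("embedding dimension reduced from ", D, " to PPMI rank ", r)
    D <- r
  }
  U <- sv$u[, seq_len(D), drop = FALSE]
  for (k in seq_len(D)) {  # deterministic sign convention
    pk <- which.max(abs(U[, k]))
    if (U[pk, k] < 0) U[, k] <- -U[, k]
  }
  vec <- U * rep(sqrt(sv$d[seq_len(D)]), each = nv)
  rownames(vec) <- vocab
  zero <- sqrt(rowSums(vec^2)) < 1e-12
  if (any(zero)) {
    message(sum(zero), " word(s) with empty co-occurrence profile given ",
            "fallback vectors")
    set.seed(seed)
    vec[zero, ] <- matrix(stats::rnorm(sum(zero) * D, sd = 1e-3),
                          ncol = D)
  }
  structure(list(vectors = vec, dims = D), class = "word_vectors")
}
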