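# shared in-code fixtures: tiny corpora, toy word vectors, and independent
# oracles used across the suite

make_tiny_corpus <- function() {
  as_corpus(data.frame(
    id = c("A1", "A2", "A3"),
    title = c("Insulin trial", "Screening methods", "Mouse model"),
    abstract = c(
      "Insulin reduces glucose rapidly. Patients improved.",
      "Reviewers screened abstracts for the systematic review.",
      "Mice ran running wheels. The mouse model runs well."
    ),
    label = c(1L, 0L, 0L),
    stringsAsFactors = FALSE
  ))
}

toy_word_vectors <- function(words, dims = 2, seed = 99) {
  set.seed(seed)
  m <- matrix(stats::rnorm(length(words) * dims), ncol = dims)
  rownames(m) <- words
  structure(list(vectors = m, dims = dims), class = "word_vectors")
}

write_ris_fixture <- function(path) {
  writeLines(c(
    "TY  - JOUR",
    "ID  - r1",
    "TI  - First study title",
    "AB  - Abstract one about insulin therapy.",
    "ER  - ",
    "TY  - JOUR",
    "ID  - r2",
    "T1  - Second study title",
    "N2  - Abstract two about screening",
    "  continued on a second line.",
    "ER  - ",
    "TY  - JOUR",
    "ID  - r3",
    "TI  - Third study",
    "AB  - Abstract three.",
    "ER  - ",
    "TY  - JOUR",
    "ID  - r4",
    "TI  - Fourth study, title only",
    "ER  - ",
    "TY  - JOUR",
    "ID  - r5",
    "TI  - Fifth study",
    "AB  - Abstract five.",
    "ER  - "
  ), path)
  path
}

# brute-force multiset counter, independent of build_dfm's sparse path
count_oracle <- function(streams, which) {
  feats <- sort(unique(unlist(lapply(streams, `[[`, which))))
  m <- t(vapply(streams, function(s) {
    v <- table(factor(s[[which]], levels = feats))
    as.numeric(v)
  }, numeric(length(feats))))
  colnames(m) <- feats
  m
}

# exact transportation LP by enumerating basic feasible solutions (spanning
# trees of the bipartite transport graph); independent of the simplex in
# the package. Feasible only for small supports.
transport_oracle <- function(a, b, C) {
  m <- length(a); n <- length(b)
  stopifnot(m * n <= 16)
  cells <- expand.grid(i = seq_len(m), j = seq_len(n))
  best <- Inf
  combs <- utils::combn(nrow(cells), m + n - 1)
  for (ci in seq_len(ncol(combs))) {
    sel <- cells[combs[, ci], ]
    # connectivity check on the bipartite node set
    g <- lapply(seq_len(m + n), function(x) integer())
    for (r in seq_len(nrow(sel))) {
      i <- sel$i[r]; j <- m + sel$j[r]
      g[[i]] <- c(g[[i]], j); g[[j]] <- c(g[[j]], i)
    }
    seen <- logical(m + n); stack <- 1L; seen[1] <- TRUE
    while (length(stack)) {
      nd <- stack[1]; stack <- stack[-1]
      for (nb in g[[nd]]) if (!seen[nb]) { seen[nb] <- TRUE; stack <- c(stack, nb) }
    }
    if (!all(seen)) next
    # solve the (m+n-1) flows from the marginal equations
    A <- matrix(0, m + n, nrow(sel))
    for (r in seq_len(nrow(sel))) {
      A[sel$i[r], r] <- 1
      A[m + sel$j[r], r] <- 1
    }
    x <- tryCatch(qr.solve(A[-1, , drop = FALSE], c(a, b)[-1]),
                  error = function(e) NULL)
    if (is.null(x) || any(x < -1e-10)) next
    cost <- sum(x * C[cbind(sel$i, sel$j)])
    if (cost < best) best <- cost
  }
  best
}
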