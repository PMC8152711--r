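streams3 <- function() {
  co <- make_tiny_corpus()
  corpus_streams(co, stopwords = character())
}

test_that("document-feature counts match a brute-force counting oracle", {
  st <- streams3()
  for (which in c("ngrams", "nouns_verbs", "words")) {
    dfm <- build_dfm(st, which)
    oracle <- count_oracle(st, which)
    expect_equal(unname(as.matrix(dfm$matrix)), unname(oracle))
    expect_identical(dfm$features, sort_c(colnames(oracle)))
  }
})

test_that("identical documents yield identical rows; empty docs get a zero row", {
  st <- list(d1 = list(words = c("x", "y", "x")),
             d2 = list(words = c("x", "y", "x")),
             d3 = list(words = character()))
  expect_warning(dfm <- build_dfm(st, "words"), "empty")
  m <- as.matrix(dfm$matrix)
  expect_equal(m["d1", ], m["d2", ])
  expect_equal(sum(m["d3", ]), 0)
  expect_error(build_dfm(list(a = list(words = character())), "words"),
               "empty")
})

test_that("feature selection keeps the smallest high-frequency prefix", {
  st <- list(d1 = list(words = c(rep("a", 6), rep("b", 3), "c")))
  dfm <- build_dfm(st, "words")
  sel <- select_common_features(dfm, 0.7)
  expect_setequal(sel$features, c("a", "b"))  # 6/10 < 0.7 <= 9/10
  expect_identical(select_common_features(dfm, 1.0)$features,
                   dfm$features)
  single <- build_dfm(list(d = list(words = "only")), "words")
  expect_equal(select_common_features(single, 0.01)$features, "only")
  expect_error(select_common_features(dfm, 0), "phi")
  expect_error(select_common_features(dfm, 1.5), "phi")
})

test_that("selection retains at least phi of token mass, never more features", {
  set.seed(7)
  st <- lapply(1:12, function(i) {
    list(words = sample(sprintf("w%02d", 1:30), rpois(1, 40), replace = TRUE))
  })
  names(st) <- paste0("d", 1:12)
  dfm <- build_dfm(st, "words")
  total <- sum(dfm$matrix)
  for (phi in c(0.3, 0.7, 0.9)) {
    sel <- select_common_features(dfm, phi)
    expect_gte(sum(sel$matrix) / total, phi - 1e-12)
    expect_lte(ncol(sel$matrix), ncol(dfm$matrix))
    # dropping the least frequent retained feature would fall below phi
    tot <- Matrix::colSums(sel$matrix)
    expect_lt((sum(tot) - min(tot)) / total, phi)
  }
})

test_that("rank-1 matrices are reconstructed exactly from one component", {
  st <- list(d1 = list(words = c("a", "b", "b")),
             d2 = list(words = c("a", "a", "b", "b", "b", "b")))
  dfm <- build_dfm(st, "words")  # rows (1,2) and (2,4): rank 1
  dv <- svd_reduce(dfm, 1)
  X <- as.matrix(dfm$matrix)
  G <- tcrossprod(X)
  expect_equal(tcrossprod(dv$matrix), G, tolerance = 1e-8)
})

test_that("full-rank scores preserve document inner products (dense SVD oracle)", {
  set.seed(11)
  st <- lapply(1:10, function(i) {
    list(words = sample(sprintf("w%02d", 1:15), 30, replace = TRUE))
  })
  names(st) <- paste0("d", 1:10)
  dfm <- build_dfm(st, "words")
  X <- as.matrix(dfm$matrix)
  r <- qr(X)$rank
  dv <- svd_reduce(dfm, r)
  expect_equal(tcrossprod(dv$matrix), tcrossprod(X),
               tolerance = 1e-6, ignore_attr = TRUE)
  # oracle route: dense svd scores agree up to column signs
  sv <- svd(X)
  oracle <- sv$u[, 1:r] %*% diag(sv$d[1:r], r)
  expect_equal(abs(crossprod(dv$matrix)), abs(crossprod(oracle)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("requesting more dimensions than rank reduces with a warning", {
  st <- list(d1 = list(words = c("a", "b")), d2 = list(words = c("a", "b")))
  dfm <- build_dfm(st, "words")
  expect_warning(dv <- svd_reduce(dfm, 5), "rank")
  expect_lt(dv$dims, 5)
})

test_that("cosine distances are invariant under exact-rank reduction", {
  set.seed(3)
  st <- lapply(1:8, function(i) {
    list(words = sample(sprintf("w%02d", 1:12), 25, replace = TRUE))
  })
  names(st) <- paste0("d", 1:8)
  dfm <- build_dfm(st, "words")
  X <- as.matrix(dfm$matrix)
  dv <- svd_reduce(dfm, qr(X)$rank)
  expect_equal(cosine_distance_matrix(dv$matrix),
               cosine_distance_matrix(X), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("degenerate one-topic model yields the unit distribution", {
  st <- streams3()
  dfm <- build_dfm(st, "nouns_verbs")
  dv <- fit_topics(dfm, T = 1, seed = 5)
  expect_equal(unname(dv$matrix[, 1]), rep(1, nrow(dv$matrix)))
})

test_that("topic rows live on the simplex and the fit is seed-reproducible", {
  st <- streams3()
  dfm <- build_dfm(st, "nouns_verbs")
  dv <- fit_topics(dfm, T = 3, seed = 5, n_iter = 50)
  expect_true(all(dv$matrix >= 0))
  expect_equal(unname(rowSums(dv$matrix)), rep(1, nrow(dv$matrix)),
               tolerance = 1e-8)
  dv2 <- fit_topics(dfm, T = 3, seed = 5, n_iter = 50)
  expect_identical(dv$matrix, dv2$matrix)
  expect_error(fit_topics(dfm, T = 10000, seed = 1), "vocabulary")
})

test_that("topics recover planted disjoint-vocabulary groups", {
  set.seed(21)
  vocabs <- list(sprintf("a%02d", 1:10), sprintf("b%02d", 1:10),
                 sprintf("c%02d", 1:10))
  st <- lapply(1:30, function(i) {
    g <- (i - 1) %/% 10 + 1
    list(nouns_verbs = sample(vocabs[[g]], 40, replace = TRUE))
  })
  names(st) <- paste0("d", 1:30)
  dfm <- build_dfm(st, "nouns_verbs")
  dv <- fit_topics(dfm, T = 3, seed = 17, n_iter = 200)
  S <- 1 - cosine_distance_matrix(dv$matrix)
  grp <- rep(1:3, each = 10)
  within <- mean(S[outer(grp, grp, "==") & upper.tri(S)])
  between <- mean(S[outer(grp, grp, "!=") & upper.tri(S)])
  expect_gt(within, between)
})

test_that("embedding rows equal hand-computed weighted averages", {
  wv <- structure(list(vectors = rbind(w = c(1, 0), u = c(0, 2)), dims = 2),
                  class = "word_vectors")
  st <- list(d1 = list(words = "w"),
             d2 = list(words = c("w", "w", "u", "u")),
             d3 = list(words = c("w", "w", "w", "u")))
  dfm <- build_dfm(st, "words")
  dv <- embed_docs(dfm, wv)
  expect_equal(unname(dv$matrix["d1", ]), c(1, 0))
  expect_equal(unname(dv$matrix["d2", ]), c(1 / 2, 1))          # (v_w+v_u)/2
  expect_equal(unname(dv$matrix["d3", ]), c(3 / 4, 1 / 2))      # (3v_w+v_u)/4
})

test_that("embedding is scale-free in counts and flags OOV-only documents", {
  wv <- toy_word_vectors(c("w", "u"), dims = 3)
  st <- list(d1 = list(words = c("w", "u", "u")),
             d2 = list(words = rep(c("w", "u", "u"), 2)),
             d3 = list(words = c("zz", "zz")))
  dfm <- build_dfm(st, "words")
  expect_warning(dv <- embed_docs(dfm, wv), "in-vocabulary")
  expect_equal(dv$matrix["d1", ], dv$matrix["d2", ])
  expect_identical(dv$flagged, "d3")
})

test_that("word-vector files parse, reject ragged lines, and round-trip", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("alpha 0.5 -1 2", "beta 1 2 3"), p)
  wv <- load_word_vectors(p)
  expect_equal(nrow(wv$vectors), 2L)
  expect_equal(wv$dims, 3L)
  expect_equal(unname(wv$vectors["alpha", ]), c(0.5, -1, 2))

  writeLines(c("alpha 0.5 -1 2", "beta 1 2 3 4"), p)
  expect_error(load_word_vectors(p), "line 2")

  wv2 <- toy_word_vectors(c("x", "y", "z"), dims = 4)
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_word_vectors(wv2, p2)
  back <- load_word_vectors(p2)
  expect_equal(back$vectors, wv2$vectors, tolerance = 1e-12)

  writeLines(c("dup 1 2", "dup 3 4"), p)
  expect_warning(wv3 <- load_word_vectors(p), "duplicate")
  expect_equal(unname(wv3$vectors["dup", ]), c(3, 4))
})
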