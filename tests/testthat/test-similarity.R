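test_that("cosine distance identities hold", {
  u <- c(1, 2, 3)
  expect_equal(cosine_distance(u, u), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 5)), 1)
  expect_equal(cosine_distance(c(1, 0), c(-2, 0)), 2)
  expect_error(cosine_distance(u, c(0, 0, 0)), "zero")
})

test_that("distance matrix matches the brute-force double loop", {
  set.seed(13)
  X <- matrix(rnorm(50), 10, 5)
  D <- cosine_distance_matrix(X)
  for (i in 1:10) for (j in 1:10) {
    expected <- if (i == j) 0 else cosine_distance(X[i, ], X[j, ])
    expect_equal(D[i, j], expected, tolerance = 1e-10)
  }
})

test_that("word-mover distance degenerates correctly", {
  wv <- toy_word_vectors(c("w", "u", "v"), dims = 3)
  bow <- function(...) {
    x <- c(...)
    stats::setNames(as.numeric(x), names(x))
  }
  a <- bow(w = 2, u = 1)
  expect_equal(wmd_distance(a, a, wv), 0, tolerance = 1e-10)
  # single-word docs: one unit of mass, one route
  d <- wmd_distance(bow(w = 3), bow(u = 1), wv)
  expect_equal(d, cosine_distance(wv$vectors["w", ], wv$vectors["u", ]),
               tolerance = 1e-10)
  expect_error(wmd_distance(bow(zz = 1), a, wv), "in-vocabulary")
})

test_that("exact transport agrees with the LP vertex-enumeration oracle", {
  set.seed(29)
  words <- sprintf("t%02d", 1:8)
  wv <- toy_word_vectors(words, dims = 4, seed = 31)
  emb <- wv$vectors / sqrt(rowSums(wv$vectors^2))
  for (rep in 1:12) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    wa <- sample(words, na); wb <- sample(words, nb)
    ca <- stats::setNames(sample(1:5, na, replace = TRUE), wa)
    cb <- stats::setNames(sample(1:5, nb, replace = TRUE), wb)
    got <- wmd_distance(ca, cb, wv)
    C <- 1 - emb[wa, , drop = FALSE] %*% t(emb[wb, , drop = FALSE])
    want <- transport_oracle(ca / sum(ca), cb / sum(cb), C)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("word-mover distance is symmetric", {
  set.seed(37)
  words <- sprintf("s%02d", 1:10)
  wv <- toy_word_vectors(words, dims = 5, seed = 41)
  for (rep in 1:8) {
    a <- stats::setNames(sample(1:4, 5, replace = TRUE), sample(words, 5))
    b <- stats::setNames(sample(1:4, 5, replace = TRUE), sample(words, 5))
    expect_lt(abs(wmd_distance(a, b, wv) - wmd_distance(b, a, wv)), 1e-10)
  }
})

test_that("relaxed mode is a lower bound on the exact distance", {
  set.seed(43)
  words <- sprintf("r%02d", 1:12)
  wv <- toy_word_vectors(words, dims = 4, seed = 47)
  for (rep in 1:10) {
    a <- stats::setNames(sample(1:3, 6, replace = TRUE), sample(words, 6))
    b <- stats::setNames(sample(1:3, 6, replace = TRUE), sample(words, 6))
    expect_lte(wmd_distance(a, b, wv, exact = FALSE),
               wmd_distance(a, b, wv) + 1e-10)
  }
})

make_vec_provider <- function(n = 20, d = 4, seed = 51) {
  set.seed(seed)
  m <- matrix(rnorm(n * d), n, d)
  rownames(m) <- sprintf("d%03d", seq_len(n))
  vector_provider(doc_vectors(m, "svd"))
}

test_that("provider queries are sorted, self-free and prefix-stable", {
  pr <- make_vec_provider()
  q5 <- pr$query("d001", 5)
  expect_false("d001" %in% q5$id)
  expect_true(!is.unsorted(q5$distance))
  q10 <- pr$query("d001", 10)
  expect_identical(q10$id[1:5], q5$id[1:5])
  expect_identical(q10$distance[1:5], q5$distance[1:5])
})

test_that("k = 1 returns the global argmin of the brute-force distances", {
  set.seed(53)
  m <- matrix(rnorm(60), 15, 4)
  rownames(m) <- sprintf("d%03d", 1:15)
  pr <- vector_provider(doc_vectors(m, "svd"))
  q <- pr$query("d005", 1)
  dists <- sapply(1:15, function(j)
    if (j == 5) Inf else cosine_distance(m[5, ], m[j, ]))
  expect_equal(q$id, rownames(m)[which.min(dists)])
})

test_that("WMD provider kNN agrees with exhaustive pairwise solves", {
  set.seed(59)
  words <- sprintf("w%02d", 1:15)
  wv <- toy_word_vectors(words, dims = 4, seed = 61)
  st <- lapply(1:30, function(i) {
    list(words = sample(words, 12, replace = TRUE))
  })
  names(st) <- sprintf("d%03d", 1:30)
  dfm <- build_dfm(st, "words")
  pr <- wmd_provider(dfm, wv)
  bows <- lapply(st, function(s) table(s$words))
  full <- sapply(names(st), function(j) {
    if (j == "d001") Inf
    else wmd_distance(bows[["d001"]], bows[[j]], wv)
  })
  got <- pr$query("d001", 5)
  ord <- order(full, names(full), method = "radix")[1:5]
  expect_equal(got$id, names(full)[ord])
  expect_equal(got$distance, unname(full[ord]), tolerance = 1e-10)
})

test_that("kNN expansion respects the size bound and exclusions", {
  pr <- make_vec_provider(n = 40)
  seeds <- c("d001", "d002", "d003")
  cand <- knn_expand(seeds, 8, list(pr))
  expect_lte(length(cand), 3 * 8 * 1)
  expect_false(any(seeds %in% cand))
  # screening more documents never grows the candidate set
  scr1 <- cand[1:5]
  c1 <- knn_expand(seeds, 8, list(pr), scr1)
  c2 <- knn_expand(seeds, 8, list(pr), c(scr1, cand[6:10]))
  expect_lte(length(c2), length(c1))
  # everything screened -> empty
  expect_length(knn_expand(seeds, 8, list(pr), pr$doc_ids), 0)
})
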