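# small synthetic corpus + workflow settings sized for fast engine tests
small_setup <- function(seed = 42, n_docs = 300) {
  co <- generate_corpus(synth_config(n_docs = n_docs, n_topics = 10,
                                     vocab_size = 200,
                                     doc_length_mean = 80, seed = seed))
  wc <- workflow_config(svd_d = 20, topics_T = 10, embed_D = 20, r = 60,
                        lda_iter = 100, n_trees = 100, seed = seed)
  list(corpus = co, config = wc)
}

test_that("perfect oracle returns exactly the reference labels", {
  co <- make_tiny_corpus()
  oracle <- reference_oracle(co)
  dec <- oracle(co$id)
  expect_equal(dec$decision, co$label)
  expect_equal(dec$reviewer1, co$label)
  # zero error rates degenerate to the perfect oracle
  oracle0 <- reference_oracle(co, error_rate = 0, seed = 5)
  expect_equal(oracle0(co$id)$decision, co$label)
  expect_error(oracle(c("A1", "missing")), "missing")
})

test_that("noisy reviewers flip at the configured rate", {
  n <- 10000
  co <- as_corpus(data.frame(
    id = sprintf("d%05d", 1:n), title = "t", abstract = "a",
    label = rep(c(0L, 1L), length.out = n), stringsAsFactors = FALSE
  ))
  oracle <- reference_oracle(co, error_rate = 0.1, seed = 77)
  dec <- oracle(co$id)
  flip1 <- mean(dec$reviewer1 != co$label)
  expect_lt(abs(flip1 - 0.1), 0.01)
  # disagreements resolve to the reference label
  dis <- dec$reviewer1 != dec$reviewer2
  expect_equal(dec$decision[dis], co$label[dis])
})

test_that("phase 1 stops once the cumulative screened count reaches r", {
  s <- small_setup()
  s$config$r <- 10
  streams <- corpus_streams(s$corpus)
  dfm <- select_common_features(build_dfm(streams, "ngrams"), 0.7)
  pr <- vector_provider(svd_reduce(dfm, 20))
  oracle <- reference_oracle(s$corpus)
  p1 <- run_phase1(s$corpus, attr(s$corpus, "seeds"), list(pr), s$config,
                   oracle)
  expect_equal(p1$iterations, 1L)
  expect_gte(nrow(p1$log), 10)
  expect_false(any(duplicated(p1$log$id)))
})

test_that("phase 1 warns and stops when expansion exhausts the corpus", {
  co <- generate_corpus(synth_config(n_docs = 40, prevalence = 0.2,
                                     n_topics = 5, eligible_topic_ids = 1,
                                     vocab_size = 80, doc_length_mean = 40,
                                     n_seeds = 3, seed = 8))
  streams <- corpus_streams(co)
  dfm <- build_dfm(streams, "words")
  pr <- vector_provider(svd_reduce(dfm, 10))
  wc <- workflow_config(r = 1000, svd_d = 10, seed = 8)
  expect_warning(
    p1 <- run_phase1(co, attr(co, "seeds"), list(pr), wc,
                     reference_oracle(co)),
    "exhausted"
  )
  expect_lt(nrow(p1$log), 1000)
})

test_that("the end-to-end run is reproducible and never re-screens a document", {
  s <- small_setup()
  r1 <- screen_corpus(s$corpus, s$config, keep_representations = FALSE)
  r2 <- screen_corpus(s$corpus, s$config, keep_representations = FALSE)
  expect_identical(r1$log, r2$log)
  expect_false(any(duplicated(r1$log$id)))
  # with a perfect oracle the workflow never includes a false positive
  truth <- stats::setNames(s$corpus$label, s$corpus$id)
  expect_true(all(truth[r1$included] == 1))
  expect_true(all(r1$included %in% r1$screened))
  expect_true(all(r1$screened %in% s$corpus$id))
  expect_lte(r1$iterations_run, s$config$max_iterations)
})

test_that("phase 2 saturates when an iteration confirms nothing new", {
  s <- small_setup()
  res <- screen_corpus(s$corpus, s$config, keep_representations = FALSE)
  last <- res$iteration_summary[nrow(res$iteration_summary), ]
  expect_equal(last$n_new_eligible, 0L)
  expect_false(res$capped)
  # screened set grows strictly in every non-final iteration
  its <- res$iteration_summary
  if (nrow(its) > 1) {
    grow <- its$n_screened_predicted[-nrow(its)] +
      its$n_screened_neighbours[-nrow(its)]
    expect_true(all(grow > 0))
  }
})

test_that("flat key = value config files round-trip into workflow_config", {
  p <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("k1 = 4", "k2 = 9", "r = 120", "phi = 0.8",
               "# a comment", "n_providers = 2"), p)
  wc <- read_workflow_config(p)
  expect_equal(wc$k1, 4L)
  expect_equal(wc$k2, 9L)
  expect_equal(wc$r, 120L)
  expect_equal(wc$phi, 0.8)
  expect_equal(wc$n_providers, 2L)
  writeLines("bogus_key = 1", p)
  expect_error(read_workflow_config(p), "unknown config key")
})
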