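#' Workflow configuration
#'
#' All tunable parameters of the two-phase screening workflow. Defaults are
#' the main-analysis settings: 8 neighbours per seed in phase 1, 15 in
#' phase 2, phase-1 target training-set size 600, feature-mass threshold
#' 0.70, 300-dimensional representations, and 3 distance measures. A single
#' master seed derives the per-component seeds (LDA, SMOTE, random forest,
#' reviewer noise) by fixed offsets.
#'
#' @param k1 Phase-1 neighbours per seed (default 8).
#' @param k2 Phase-2 neighbours per newly eligible document (default 15).
#' @param r Phase-1 target cumulative screened count (default 600).
#' @param phi Feature-mass threshold in (0, 1] for n-gram selection
#'   (default 0.70).
#' @param svd_d,topics_T,embed_D Representation sizes (defaults 300).
#' @param n_providers 2 (SVD + embedding distances) or 3 (adds topics).
#' @param seed Master RNG seed.
#' @param max_iterations Phase-2 safety cap (default 25).
#' @param lda_iter Gibbs sweeps for the topic model (default 500).
#' @param wmd_cap Per-document word cap for the transport problem
#'   (default 50; `Inf` disables).
#' @param wmd_exact Exact word-mover distance (default) or relaxed bound.
#' @param n_trees,n_folds,smote_k,threshold Classifier settings, see
#'   [classifier_spec()].
#' @return A `workflow_config` list.
#' @export
workflow_config <- function(k1 = 8, k2 = 15, r = 600, phi = 0.70,
                            svd_d = 300, topics_T = 300, embed_D = 300,
                            n_providers = 3, seed = 1,
                            max_iterations = 25, lda_iter = 500,
                            wmd_cap = 50, wmd_exact = TRUE,
                            n_trees = 500, n_folds = 5, smote_k = 5,
                            threshold = 0.5) {
  stopifnot(k1 >= 1, k2 >= 1, r >= 1, phi > 0, phi <= 1,
            max_iterations >= 1, n_providers %in% c(2, 3))
  structure(list(
    k1 = as.integer(k1), k2 = as.integer(k2), r = as.integer(r), phi = phi,
    svd_d = as.integer(svd_d), topics_T = as.integer(topics_T),
    embed_D = as.integer(embed_D), n_providers = as.integer(n_providers),
    seed = as.integer(seed), max_iterations = as.integer(max_iterations),
    lda_iter = as.integer(lda_iter), wmd_cap = wmd_cap,
    wmd_exact = isTRUE(wmd_exact), n_trees = as.integer(n_trees),
    n_folds = as.integer(n_folds), smote_k = as.integer(smote_k),
    threshold = threshold
  ), class = "workflow_config")
}

# fixed offsets deriving per-component seeds from the master seed
component_seed <- function(config, component) {
  off <- c(lda = 101L, smote = 211L, rf = 307L, noise = 401L,
           embed = 503L)[[component]]
  (config$seed + off) %% .Machine$integer.max
}

#' Read a flat key = value workflow configuration file
#'
#' Unknown keys raise an error; values are coerced to the type of the
#' corresponding [workflow_config()] default.
#'
#' @param path File path.
#' @return A `workflow_config`.
#' @export
read_workflow_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  defaults <- workflow_config()
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    args[[key]] <- if (is.logical(defaults[[key]])) {
      toupper(val) %in% c("TRUE", "T", "1", "YES")
    } else {
      as.numeric(val)
    }
  }
  do.call(workflow_config, args)
}

#' Simulated dual-reviewer screening oracle
#'
#' Builds a reviewer model from the corpus reference labels. With
#' `error_rate = 0` both simulated reviewers return the reference label.
#' With noise, each reviewer independently flips the reference decision
#' with probability `error_rate`; disagreements are adjudicated back to the
#' reference label (consensus assumption), so a wrong final decision needs
#' both reviewers to err.
#'
#' @param corpus A `screen_corpus` with reference labels for every
#'   citation that may be screened.
#' @param error_rate Per-reviewer flip probability (default 0).
#' @param seed Integer seed for the noise stream.
#' @return A function `(doc_ids) -> data.frame(id, reviewer1, reviewer2,
#'   decision)`.
#' @export
reference_oracle <- function(corpus, error_rate = 0, seed = 1L) {
  labels <- stats::setNames(corpus$label, corpus$id)
  rng <- new.env(parent = emptyenv())
  rng$state <- as.integer(seed)
  function(doc_ids) {
    ref <- labels[doc_ids]
    if (anyNA(ref)) {
      stop("missing reference label for: ",
           paste(doc_ids[is.na(ref)], collapse = ", "))
    }
    n <- length(doc_ids)
    if (error_rate > 0) {
      flips <- local({
        set.seed(rng$state)
        matrix(stats::runif(2 * n) < error_rate, ncol = 2)
      })
      rng$state <- (rng$state + 1L) %% .Machine$integer.max
      r1 <- ifelse(flips[, 1], 1L - ref, ref)
      r2 <- ifelse(flips[, 2], 1L - ref, ref)
      decision <- ifelse(r1 == r2, r1, ref)
    } else {
      r1 <- r2 <- decision <- ref
    }
    data.frame(id = doc_ids, reviewer1 = as.integer(r1),
               reviewer2 = as.integer(r2),
               decision = as.integer(decision),
               stringsAsFactors = FALSE, row.names = NULL)
  }
}

new_screening_log <- function() {
  data.frame(id = character(), phase = integer(), iteration = integer(),
             batch_kind = character(), reviewer1 = integer(),
             reviewer2 = integer(), decision = integer(),
             stringsAsFactors = FALSE)
}

log_append <- function(log, decisions, phase, iteration, batch_kind) {
  if (any(decisions$id %in% log$id)) {
    stop("internal error: document screened twice: ",
         paste(intersect(decisions$id, log$id), collapse = ", "))
  }
  rbind(log, data.frame(
    id = decisions$id, phase = phase, iteration = iteration,
    batch_kind = batch_kind, reviewer1 = decisions$reviewer1,
    reviewer2 = decisions$reviewer2, decision = decisions$decision,
    stringsAsFactors = FALSE
  ))
}

#' Phase 1: grow the training set by nearest-neighbour seed expansion
#'
#' Starting from a handful of confirmed-eligible seed abstracts, repeatedly
#' identifies the `k1` nearest neighbours of every currently eligible
#' document under each distance provider, has the (simulated) reviewer pair
#' screen the batch, and adds the results, until the cumulative number of
#' screened documents reaches the pre-set training-set size `r` or no new
#' candidates exist.
#'
#' @param corpus A `screen_corpus`.
#' @param seeds Character vector of eligible doc ids (3-5 typical).
#' @param providers List of `distance_provider` objects.
#' @param config A [workflow_config()].
#' @param oracle Screening function, e.g. [reference_oracle()].
#' @return List with `log` (the phase-1 `ScreeningLog`), `eligible`
#'   (confirmed-eligible ids including seeds), and `screened`.
#' @export
run_phase1 <- function(corpus, seeds, providers, config, oracle) {
  if (length(seeds) == 0) stop("phase 1 requires at least one eligible seed")
  if (!all(seeds %in% corpus$id)) {
    stop("seed id(s) not in corpus: ",
         paste(setdiff(seeds, corpus$id), collapse = ", "))
  }
  log <- new_screening_log()
  seed_dec <- data.frame(id = seeds, reviewer1 = 1L, reviewer2 = 1L,
                         decision = 1L, stringsAsFactors = FALSE)
  log <- log_append(log, seed_dec, 1L, 0L, "seed")
  eligible <- seeds
  iter <- 0L
  repeat {
    if (nrow(log) >= config$r) break
    iter <- iter + 1L
    cand <- knn_expand(eligible, config$k1, providers, log$id)
    if (length(cand) == 0) {
      warning("phase 1 exhausted all neighbours after screening ",
              nrow(log), " documents (target r = ", config$r, ")")
      break
    }
    dec <- oracle(cand)
    log <- log_append(log, dec, 1L, iter, "seed_expansion")
    eligible <- c(eligible, dec$id[dec$decision == 1L])
  }
  list(log = log, eligible = eligible, screened = log$id,
       iterations = iter)
}

#' Phase 2: iterative classify-screen-expand loop to saturation
#'
#' Repeats: fit the SMOTE-balanced random forest to all screening decisions
#' so far, predict eligible documents over the whole corpus, have reviewers
#' screen the unscreened predictions, expand every not-yet-expanded
#' confirmed-eligible document by its `k2` nearest neighbours, screen
#' those too, and fold every decision into the next training set. Every
#' confirmed eligible receives exactly one `k2` expansion during phase 2 —
#' including the eligibles inherited from phase 1, whose neighbourhoods
#' were only explored at the shallower `k1` there.
#' The loop reaches saturation — and stops — when an iteration confirms no
#' new eligible document anywhere, i.e. the predicted batch adds nothing
#' and no confirmed eligible is left unexpanded; `max_iterations` caps
#' runaway loops (result flagged `capped`).
#'
#' @param corpus A `screen_corpus`.
#' @param phase1 Result of [run_phase1()].
#' @param svd_vectors `doc_vectors` of kind `"svd"` over the corpus.
#' @param providers List of `distance_provider` objects.
#' @param config A [workflow_config()].
#' @param oracle Screening function.
#' @return A `workflow_result`: list with `included` (confirmed-eligible
#'   ids), `predicted_ever`, `screened`, `iterations_run`, `capped`, `log`,
#'   and `iteration_summary`.
#' @export
run_phase2 <- function(corpus, phase1, svd_vectors, providers, config,
                       oracle) {
  log <- phase1$log
  predicted_ever <- character()
  capped <- FALSE
  iter <- 0L
  summaries <- list()
  # confirmed eligibles awaiting their phase-2 (k2) expansion; phase-1
  # eligibles start here because phase 1 only expanded them at k1
  unexpanded <- unique(phase1$eligible)
  repeat {
    if (iter >= config$max_iterations) {
      capped <- TRUE
      warning("phase 2 reached max_iterations = ", config$max_iterations,
              " before saturation; result flagged 'capped'")
      break
    }
    iter <- iter + 1L
    spec <- classifier_spec(
      n_trees = config$n_trees, n_folds = config$n_folds,
      smote_k = config$smote_k, threshold = config$threshold,
      seed = component_seed(config, "rf") + iter
    )
    train <- training_set(log$id, log$decision, svd_vectors)
    model <- train_rf_cv(train, spec)
    predicted <- predict_eligible(model, svd_vectors)
    predicted_ever <- union(predicted_ever, predicted)
    to_screen <- sort_c(setdiff(predicted, log$id))
    new_eligible <- character()
    if (length(to_screen)) {
      dec <- oracle(to_screen)
      log <- log_append(log, dec, 2L, iter, "predicted")
      new_eligible <- dec$id[dec$decision == 1L]
    }
    unexpanded <- union(unexpanded, new_eligible)
    summaries[[iter]] <- data.frame(
      iteration = iter, n_predicted = length(predicted),
      n_screened_predicted = length(to_screen),
      n_new_eligible = length(new_eligible),
      n_screened_neighbours = 0L,
      cv_sensitivity = max(model$cv_sensitivity, na.rm = TRUE),
      mtry = model$mtry
    )
    if (length(unexpanded) == 0) break  # saturation: nothing new anywhere
    nbrs <- knn_expand(unexpanded, config$k2, providers, log$id)
    unexpanded <- character()
    if (length(nbrs)) {
      dec <- oracle(nbrs)
      log <- log_append(log, dec, 2L, iter, "neighbour")
      unexpanded <- dec$id[dec$decision == 1L]
    }
    summaries[[iter]]$n_screened_neighbours <- length(nbrs)
  }
  structure(list(
    included = log$id[log$decision == 1L],
    predicted_ever = predicted_ever,
    screened = log$id,
    iterations_run = iter,
    capped = capped,
    log = log,
    iteration_summary = do.call(rbind, summaries)
  ), class = "workflow_result")
}

#' @export
print.workflow_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<workflow_result> %d iterations%s: %d screened, %d eligible ",
    "identified, %d ever predicted\n"),
    x$iterations_run, if (x$capped) " (capped)" else "",
    length(x$screened), length(x$included), length(x$predicted_ever)))
  invisible(x)
}

#' Run the complete two-phase screening workflow
#'
#' Builds the three document representations once up front (n-gram SVD,
#' noun/verb topic model, frequency-weighted word embeddings), constructs
#' the distance providers, grows the training set from the seeds
#' (phase 1), then iterates the classify-screen-expand loop to saturation
#' (phase 2).
#'
#' @param corpus A `screen_corpus` (title-only records are filtered out
#'   first; a message reports how many).
#' @param config A [workflow_config()].
#' @param seeds Eligible seed ids; defaults to the corpus `seeds`
#'   attribute (set by [generate_corpus()]).
#' @param oracle Screening function; defaults to a perfect
#'   [reference_oracle()] over the corpus labels.
#' @param word_vectors A `word_vectors` object; defaults to
#'   [train_toy_embeddings()] on the corpus itself (suitable for synthetic
#'   corpora; supply pretrained vectors for real screening).
#' @param stopwords Stop-word list.
#' @param pos_lexicon Optional lemma -> POS lexicon.
#' @param keep_representations Keep matrices/vectors on the result
#'   (default TRUE).
#' @return A `screen_result` object; see [run_phase2()] for the core
#'   fields. Also carries `phase1`, `config`, `timings`, and the
#'   representations when kept.
#' @export
screen_corpus <- function(corpus, config = workflow_config(),
                          seeds = attr(corpus, "seeds"),
                          oracle = NULL, word_vectors = NULL,
                          stopwords = default_stopwords(),
                          pos_lexicon = attr(corpus, "pos_lexicon"),
                          keep_representations = TRUE) {
  stopifnot(inherits(corpus, "screen_corpus"),
            inherits(config, "workflow_config"))
  t0 <- proc.time()[["elapsed"]]
  corpus <- filter_title_only(corpus)
  if (is.null(seeds) || !length(seeds)) {
    stop("no seed abstracts supplied (and corpus has no 'seeds' attribute)")
  }
  if (is.null(oracle)) {
    if (anyNA(corpus$label)) {
      stop("corpus lacks reference labels; supply an oracle")
    }
    oracle <- reference_oracle(corpus, seed = component_seed(config, "noise"))
  }
  streams <- corpus_streams(corpus, stopwords, pos_lexicon)
  dfm_ngram <- select_common_features(build_dfm(streams, "ngrams"),
                                      config$phi)
  dfm_nv <- build_dfm(streams, "nouns_verbs")
  dfm_words <- build_dfm(streams, "words")
  if (is.null(word_vectors)) {
    word_vectors <- train_toy_embeddings(corpus, D = config$embed_D,
                                         seed = component_seed(config,
                                                               "embed"))
  }
  svd_vecs <- svd_reduce(dfm_ngram, config$svd_d)
  providers <- list(vector_provider(svd_vecs))
  if (config$n_providers == 3) {
    topic_vecs <- fit_topics(dfm_nv, config$topics_T,
                             seed = component_seed(config, "lda"),
                             n_iter = config$lda_iter)
    providers <- c(providers, list(vector_provider(topic_vecs)))
  } else {
    topic_vecs <- NULL
  }
  emb_vecs <- embed_docs(dfm_words, word_vectors)
  providers <- c(providers, list(
    wmd_provider(dfm_words, word_vectors, cap = config$wmd_cap,
                 exact = config$wmd_exact)))
  t1 <- proc.time()[["elapsed"]]
  p1 <- run_phase1(corpus, seeds, providers, config, oracle)
  t2 <- proc.time()[["elapsed"]]
  res <- run_phase2(corpus, p1, svd_vecs, providers, config, oracle)
  t3 <- proc.time()[["elapsed"]]
  res$phase1 <- p1
  res$config <- config
  res$seeds <- seeds
  res$corpus_ids <- corpus$id
  res$N <- nrow(corpus)
  res$timings <- c(representations = t1 - t0, phase1 = t2 - t1,
                   phase2 = t3 - t2)
  if (keep_representations) {
    res$representations <- list(svd = svd_vecs, topic = topic_vecs,
                                embedding = emb_vecs)
  }
  class(res) <- c("screen_result", class(res))
  res
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Two-phase screening workflow result\n")
  cat(sprintf("  corpus: %d citations; seeds: %d\n", x$N, length(x$seeds)))
  cat(sprintf("  phase 1: %d screened in %d expansion(s), %d eligible\n",
              nrow(x$phase1$log), x$phase1$iterations,
              length(x$phase1$eligible)))
  cat(sprintf("  phase 2: %d iteration(s)%s, %d screened in total\n",
              x$iterations_run, if (x$capped) " (capped)" else "",
              length(x$screened)))
  cat(sprintf("  eligible identified: %d; ever predicted eligible: %d\n",
              length(x$included), length(x$predicted_ever)))
  invisible(x)
}

#' @export
summary.screen_result <- function(object, ...) {
  print(object)
  cat("\nPer-iteration phase-2 summary:\n")
  print(object$iteration_summary, row.names = FALSE)
  invisible(object)
}
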