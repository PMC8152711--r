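library(screenflow)
for (seed in c(2, 5)) {
  co <- generate_corpus(synth_config(seed = seed))
  wc <- workflow_config(svd_d = 50, topics_T = 50, embed_D = 50, seed = seed)
  res <- suppressWarnings(screen_corpus(co, wc))
  found <- intersect(res$included, co$id[co$label == 1])
  missed <- setdiff(co$id[co$label == 1], res$screened)
  sv <- res$representations$svd
  # reachability: is any missed eligible inside the k2-neighbourhood of any
  # found eligible under the SVD distance?
  pr <- vector_provider(sv)
  reach <- unique(unlist(lapply(found, function(s) pr$query(s, 15)$id)))
  cat(sprintf("seed %d: missed %d, reachable via svd k2-nbhd: %d\n",
              seed, length(missed), length(intersect(missed, reach))))
  # classifier ranking: rank of missed eligibles among unscreened docs
  train <- training_set(res$log$id, res$log$decision, sv)
  fit <- train_rf_cv(train, classifier_spec(seed = 99))
  p <- predict_probabilities(fit, sv)
  unscreened <- setdiff(co$id, res$screened)
  r <- rank(-p[unscreened])
  cat("ranks of missed eligibles among", length(unscreened),
      "unscreened docs:\n")
  print(sort(round(r[missed])))
}
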