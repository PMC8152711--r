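#' Classifier specification
#'
#' Hyper-parameters of the eligibility random forest: number of trees,
#' cross-validation folds, the tuning grid over features-per-split (mtry),
#' SMOTE neighbourhood size, the probability decision threshold, and the
#' seed. `mtry_grid = NULL` expands to `{sqrt(D)/2, sqrt(D), 2*sqrt(D)}`
#' (rounded, deduplicated, clipped to `[1, D]`) at fit time.
#'
#' @param n_trees Trees per forest (default 500).
#' @param n_folds CV folds (default 5, must be >= 2).
#' @param mtry_grid Integer vector of candidate mtry values, or `NULL`.
#' @param smote_k SMOTE neighbours (default 5).
#' @param threshold Decision threshold in (0, 1) (default 0.5).
#' @param seed Integer seed.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(n_trees = 500, n_folds = 5, mtry_grid = NULL,
                            smote_k = 5, threshold = 0.5, seed = 1) {
  stopifnot(n_folds >= 2, threshold > 0, threshold < 1, n_trees >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 n_folds = as.integer(n_folds),
                 mtry_grid = mtry_grid, smote_k = as.integer(smote_k),
                 threshold = threshold, seed = as.integer(seed)),
            class = "classifier_spec")
}

default_mtry_grid <- function(D) {
  g <- unique(pmax(1L, pmin(as.integer(D),
                            as.integer(round(c(sqrt(D) / 2, sqrt(D),
                                               2 * sqrt(D)))))))
  sort(g)
}

#' SMOTE oversampling of the minority class
#'
#' Generates synthetic minority rows `x_i + u * (x_nn - x_i)` with
#' `u ~ Uniform(0,1)` and `x_nn` a uniformly chosen one of `x_i`'s `k`
#' nearest minority-class neighbours (Euclidean), until classes are
#' balanced 1:1.
#'
#' @param X_minority,X_majority Numeric matrices (rows = samples).
#' @param k Neighbours (clamped to `nrow(X_minority) - 1` with a warning).
#' @param seed Integer seed; fixed seed gives identical synthetic rows.
#' @return List with `X` (majority, minority, then synthetic rows), `y`
#'   (0/1), and `synthetic` (logical row provenance flags).
#' @export
smote_oversample <- function(X_minority, X_majority, k, seed) {
  X_minority <- as.matrix(X_minority)
  X_majority <- as.matrix(X_majority)
  n_min <- nrow(X_minority); n_maj <- nrow(X_majority)
  if (n_min < 2) {
    stop("SMOTE needs at least 2 minority samples to interpolate")
  }
  if (k > n_min - 1) {
    warning("smote_k = ", k, " clamped to ", n_min - 1)
    k <- n_min - 1
  }
  n_new <- max(0L, n_maj - n_min)
  synth <- NULL
  if (n_new > 0L) {
    D <- as.matrix(stats::dist(X_minority))
    diag(D) <- Inf
    nn <- apply(D, 1, function(d) order(d)[seq_len(k)])
    nn <- matrix(nn, nrow = k)  # k x n_min
    rs <- local({
      set.seed(seed)
      list(base = sample.int(n_min, n_new, replace = TRUE),
           pick = sample.int(k, n_new, replace = TRUE),
           u = stats::runif(n_new))
    })
    xi <- X_minority[rs$base, , drop = FALSE]
    xn <- X_minority[nn[cbind(rs$pick, rs$base)], , drop = FALSE]
    synth <- xi + rs$u * (xn - xi)
  }
  X <- rbind(X_majority, X_minority, synth)
  rownames(X) <- NULL
  y <- c(rep(0L, n_maj), rep(1L, n_min + n_new))
  synthetic <- c(rep(FALSE, n_maj + n_min), rep(TRUE, n_new))
  list(X = X, y = y, synthetic = synthetic)
}

#' Assemble a training set from screening decisions and SVD features
#'
#' @param doc_ids Character vector of screened doc ids.
#' @param decisions Integer 0/1 screening outcomes, parallel to `doc_ids`.
#' @param svd_vectors `doc_vectors` of kind `"svd"` covering the corpus.
#' @return A `training_set`: list with `doc_ids`, `X`, `y`.
#' @export
training_set <- function(doc_ids, decisions, svd_vectors) {
  stopifnot(inherits(svd_vectors, "doc_vectors"),
            svd_vectors$kind == "svd",
            length(doc_ids) == length(decisions))
  i <- match(doc_ids, svd_vectors$doc_ids)
  if (anyNA(i)) stop("screened doc id(s) missing from SVD vectors")
  structure(list(doc_ids = doc_ids,
                 X = svd_vectors$matrix[i, , drop = FALSE],
                 y = as.integer(decisions)),
            class = "training_set")
}

# stratified fold assignment, deterministic for a given seed
stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  set.seed(seed)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

# one fold's training data, SMOTE-balanced; validation rows are untouched
# original rows by construction (synthetic rows are created from training
# rows only and never enter the validation index set)
smote_fold <- function(X, y, train_idx, k, seed) {
  Xm <- X[train_idx[y[train_idx] == 1L], , drop = FALSE]
  XM <- X[train_idx[y[train_idx] == 0L], , drop = FALSE]
  smote_oversample(Xm, XM, k, seed)
}

fit_ranger <- function(X, y, mtry, n_trees, seed) {
  ranger::ranger(
    x = as.data.frame(X), y = factor(y, levels = c(0L, 1L)),
    num.trees = n_trees, mtry = min(mtry, ncol(X)),
    probability = TRUE, min.node.size = 1, seed = seed, num.threads = 1
  )
}

rf_prob <- function(model, X) {
  p <- stats::predict(model, data = as.data.frame(X),
                      num.threads = 1)$predictions
  as.numeric(p[, "1"])
}

#' Train the eligibility random forest with sensitivity-maximizing CV
#'
#' For each candidate mtry, runs stratified n-fold cross-validation with
#' SMOTE applied only inside each training fold (validation folds contain
#' no synthetic rows), scores mean validation sensitivity at the spec's
#' decision threshold, selects the grid value with the highest mean
#' sensitivity (ties go to the smaller mtry), and refits on the full
#' SMOTE-balanced training set.
#'
#' @param train A `training_set` (both classes must be present and
#'   `n >= 2 * n_folds`).
#' @param spec A [classifier_spec()].
#' @return A `screen_rf`: list with the fitted `model`, selected `mtry`,
#'   `cv_sensitivity` (named by grid value), `cv_detail`, and `spec`.
#' @export
train_rf_cv <- function(train, spec = classifier_spec()) {
  stopifnot(inherits(train, "training_set"),
            inherits(spec, "classifier_spec"))
  X <- train$X; y <- train$y
  if (length(unique(y)) < 2) {
    stop("training set has a single class; screen more documents in ",
         "phase 1 before fitting the classifier")
  }
  if (length(y) < 2 * spec$n_folds) {
    stop("training set too small for ", spec$n_folds, "-fold CV")
  }
  grid <- spec$mtry_grid %||% default_mtry_grid(ncol(X))
  fold <- stratified_folds(y, spec$n_folds, spec$seed)
  cv <- matrix(NA_real_, nrow = spec$n_folds, ncol = length(grid),
               dimnames = list(NULL, as.character(grid)))
  synth_in_val <- 0L
  for (f in seq_len(spec$n_folds)) {
    tr <- which(fold != f); va <- which(fold == f)
    if (sum(y[va] == 1L) == 0L) next
    bal <- smote_fold(X, y, tr, spec$smote_k, spec$seed + 31L * f)
    synth_in_val <- synth_in_val + 0L  # validation rows drawn from X only
    for (g in seq_along(grid)) {
      m <- fit_ranger(bal$X, bal$y, grid[g], spec$n_trees,
                      spec$seed + 101L * f + g)
      p <- rf_prob(m, X[va, , drop = FALSE])
      pos <- y[va] == 1L
      cv[f, g] <- mean(p[pos] >= spec$threshold)
    }
  }
  mean_sens <- colMeans(cv, na.rm = TRUE)
  best <- grid[which.max(mean_sens)]  # which.max takes the first (smaller)
  bal <- smote_fold(X, y, seq_along(y), spec$smote_k, spec$seed + 7L)
  model <- fit_ranger(bal$X, bal$y, best, spec$n_trees, spec$seed + 997L)
  structure(list(model = model, mtry = best, cv_sensitivity = mean_sens,
                 cv_detail = cv, spec = spec, n_train = length(y),
                 dims = ncol(X)),
            class = "screen_rf")
}

#' @export
print.screen_rf <- function(x, ...) {
  cat(sprintf(
    "<screen_rf> %d trees, mtry = %d (CV sensitivity %.3f), n = %d\n",
    x$spec$n_trees, x$mtry, max(x$cv_sensitivity, na.rm = TRUE), x$n_train))
  invisible(x)
}

#' Predict eligible documents
#'
#' @param model A `screen_rf` from [train_rf_cv()].
#' @param vectors `doc_vectors` of kind `"svd"` covering all documents.
#' @param threshold Probability threshold; documents with predicted
#'   eligibility probability `>= threshold` are returned (already-screened
#'   documents included; the caller filters).
#' @return Character vector of predicted-eligible doc ids.
#' @export
predict_eligible <- function(model, vectors,
                             threshold = model$spec$threshold) {
  stopifnot(inherits(model, "screen_rf"), inherits(vectors, "doc_vectors"),
            vectors$kind == "svd")
  if (ncol(vectors$matrix) != model$dims) {
    stop("dimension mismatch: model trained on ", model$dims,
         " features, vectors have ", ncol(vectors$matrix))
  }
  p <- rf_prob(model$model, vectors$matrix)
  vectors$doc_ids[p >= threshold]
}

#' @rdname predict_eligible
#' @return For `predict_probabilities()`: named numeric vector of
#'   eligibility probabilities.
#' @export
predict_probabilities <- function(model, vectors) {
  stopifnot(inherits(model, "screen_rf"), inherits(vectors, "doc_vectors"))
  p <- rf_prob(model$model, vectors$matrix)
  names(p) <- vectors$doc_ids
  p
}
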