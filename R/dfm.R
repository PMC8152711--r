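#' Build a document-feature matrix from token streams
#'
#' Counts are exact multiset counts of the chosen stream per document;
#' features are ordered lexicographically (`C` collation) and documents keep
#' corpus order. Documents whose stream is empty yield an all-zero row and
#' are retained with a warning.
#'
#' @param streams Named per-document list of stream lists, as produced by
#'   [corpus_streams()].
#' @param which One of `"ngrams"`, `"nouns_verbs"`, `"words"`.
#' @return A `dfm` object: list with `matrix` (sparse `dgCMatrix`,
#'   documents x features), `doc_ids`, `features`, `which`.
#' @export
build_dfm <- function(streams, which = c("ngrams", "nouns_verbs", "words")) {
  which <- match.arg(which)
  stopifnot(length(streams) > 0)
  toks <- lapply(streams, `[[`, which)
  lens <- lengths(toks)
  if (all(lens == 0L)) {
    stop("all documents are empty for stream '", which, "'")
  }
  flat <- unlist(toks, use.names = FALSE)
  feats <- sort_c(unique(flat))
  j <- match(flat, feats)
  i <- rep.int(seq_along(toks), lens)
  m <- Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(length(toks), length(feats)),
    dimnames = list(names(toks), feats)
  )
  m <- methods::as(m, "CsparseMatrix")
  if (any(lens == 0L)) {
    warning(sum(lens == 0L), " document(s) have an empty '", which,
            "' stream (all-zero rows retained)")
  }
  structure(
    list(matrix = m, doc_ids = names(toks), features = feats, which = which),
    class = "dfm"
  )
}

# locale-independent lexicographic sort
sort_c <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  sort(x, method = "radix")
}

#' @export
print.dfm <- function(x, ...) {
  cat(sprintf("<dfm:%s> %d documents x %d features, %d nonzero counts\n",
              x$which, nrow(x$matrix), ncol(x$matrix),
              length(x$matrix@x)))
  invisible(x)
}

#' Retain the high-frequency features covering a fraction of token mass
#'
#' Features are ranked by total corpus frequency (ties broken
#' lexicographically ascending) and the smallest prefix whose cumulative
#' frequency reaches `phi` of the total token mass is kept; documents are
#' re-projected onto the retained features.
#'
#' @param dfm A `dfm`.
#' @param phi Fraction of total token mass to retain, in (0, 1].
#' @return A `dfm` restricted to the retained features (original feature
#'   order, i.e. lexicographic, is preserved).
#' @export
select_common_features <- function(dfm, phi) {
  stopifnot(inherits(dfm, "dfm"))
  if (!is.numeric(phi) || length(phi) != 1L || phi <= 0 || phi > 1) {
    stop("phi must be a single number in (0, 1]")
  }
  tot <- Matrix::colSums(dfm$matrix)
  total_mass <- sum(tot)
  if (total_mass == 0) stop("document-feature matrix has no counts")
  # rank: frequency descending, then feature name ascending (already in
  # C-sorted column order, so a stable order() suffices)
  rk <- order(-tot)
  cum <- cumsum(tot[rk])
  n_keep <- which(cum >= phi * total_mass - 1e-12)[1]
  keep_idx <- sort(rk[seq_len(n_keep)])
  out <- dfm
  out$matrix <- dfm$matrix[, keep_idx, drop = FALSE]
  out$features <- dfm$features[keep_idx]
  out
}
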