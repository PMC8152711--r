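#' Citation corpus
#'
#' A corpus is an ordered collection of citation records (id, title,
#' abstract, optional binary reference-standard label). It is stored as a
#' `data.frame` with class `screen_corpus`; row order is the stable document
#' order used by every downstream matrix.
#'
#' @param x data.frame with columns `id`, `title`, `abstract` and optionally
#'   `label` (0/1, `NA` allowed when no reference standard exists).
#' @return A `screen_corpus` object.
#' @export
as_corpus <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("id", "title", "abstract")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("corpus is missing column(s): ", paste(miss, collapse = ", "))
  }
  x$id <- as.character(x$id)
  x$title <- as.character(x$title)
  x$abstract <- as.character(x$abstract)
  x$abstract[is.na(x$abstract)] <- ""
  if (anyNA(x$id) || any(!nzchar(x$id))) {
    stop("every citation must have a non-empty id")
  }
  dup <- unique(x$id[duplicated(x$id)])
  if (length(dup)) {
    stop("duplicate citation id(s): ", paste(dup, collapse = ", "))
  }
  if (anyNA(x$title) || any(!nzchar(trimws(x$title)))) {
    stop("every citation must have a non-empty title")
  }
  if (!is.null(x$label)) {
    lab <- x$label
    bad <- !is.na(lab) & !(lab %in% c(0, 1))
    if (any(bad)) stop("reference labels must be binary (0/1) or NA")
    x$label <- as.integer(lab)
  } else {
    x$label <- rep(NA_integer_, nrow(x))
  }
  rownames(x) <- NULL
  class(x) <- c("screen_corpus", "data.frame")
  x
}

#' @export
print.screen_corpus <- function(x, ...) {
  n_lab <- sum(!is.na(x$label))
  cat(sprintf("<screen_corpus> %d citations", nrow(x)))
  if (n_lab > 0) {
    cat(sprintf(", %d labelled (%d eligible)", n_lab,
                sum(x$label == 1L, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}

#' Number of citations in a corpus
#' @param corpus A `screen_corpus`.
#' @return Integer count.
#' @export
corpus_size <- function(corpus) nrow(corpus)

#' Read citations from RIS or CSV
#'
#' CSV files must have header columns `id,title,abstract` and may carry a
#' `label` column with the reference-standard eligibility (0/1). RIS records
#' are delimited by `ER  -` tags; the title is taken from the first
#' non-empty of `TI`/`T1`, the abstract from `AB`/`N2`, the id from an `ID`
#' tag when present (sequential ids are generated otherwise, with a
#' warning).
#'
#' @param path File path.
#' @param format `"csv"`, `"ris"`, or `"auto"` (decided by file extension).
#' @return A [as_corpus()] object preserving input order.
#' @export
read_citations <- function(path, format = c("auto", "csv", "ris")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.ris$", path, ignore.case = TRUE)) "ris" else "csv"
  }
  if (format == "csv") read_citations_csv(path) else read_citations_ris(path)
}

read_citations_csv <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !nzchar(first)) {
    return(as_corpus(data.frame(id = character(), title = character(),
                                abstract = character(),
                                stringsAsFactors = FALSE)))
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("cannot parse CSV '", path, "': ",
                             conditionMessage(e))
  )
  need <- c("id", "title", "abstract")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("CSV '", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!is.null(df$label)) {
    df$label <- suppressWarnings(as.integer(df$label))
  }
  as_corpus(df[, intersect(c("id", "title", "abstract", "label"), names(df))])
}

read_citations_ris <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(as_corpus(data.frame(id = character(), title = character(),
                                abstract = character(),
                                stringsAsFactors = FALSE)))
  }
  tag_re <- "^([A-Z][A-Z0-9])  - ?(.*)$"
  records <- list()
  cur <- NULL
  last_tag <- NULL
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (grepl(tag_re, ln)) {
      tag <- sub(tag_re, "\\1", ln)
      val <- sub(tag_re, "\\2", ln)
      if (tag == "TY") {
        cur <- list()
        last_tag <- NULL
      } else if (tag == "ER") {
        if (is.null(cur)) {
          stop("malformed RIS at line ", k, ": 'ER' without a record start")
        }
        records[[length(records) + 1L]] <- cur
        cur <- NULL
      } else {
        if (is.null(cur)) {
          stop("malformed RIS at line ", k,
               ": tag '", tag, "' outside a record (missing 'TY')")
        }
        cur[[tag]] <- c(cur[[tag]], val)
        last_tag <- tag
      }
    } else if (!is.null(cur) && !is.null(last_tag)) {
      # continuation line: append to the previous tag's value
      i <- length(cur[[last_tag]])
      cur[[last_tag]][i] <- paste(cur[[last_tag]][i], trimws(ln))
    } else {
      stop("malformed RIS at line ", k, ": unrecognised content '", ln, "'")
    }
  }
  if (!is.null(cur)) {
    stop("malformed RIS: last record (", length(records) + 1L,
         ") not terminated by 'ER'")
  }
  first_of <- function(rec, tags) {
    for (tg in tags) {
      v <- rec[[tg]]
      v <- v[nzchar(trimws(v))]
      if (length(v)) return(paste(v, collapse = " "))
    }
    ""
  }
  ids <- vapply(records, first_of, "", tags = "ID")
  if (any(!nzchar(ids))) {
    warning("RIS records without an ID tag; sequential ids assigned")
    gen <- sprintf("rec%04d", seq_along(records))
    ids[!nzchar(ids)] <- gen[!nzchar(ids)]
  }
  df <- data.frame(
    id = ids,
    title = vapply(records, first_of, "", tags = c("TI", "T1")),
    abstract = vapply(records, first_of, "", tags = c("AB", "N2")),
    stringsAsFactors = FALSE
  )
  lab <- vapply(records, first_of, "", tags = "LB")
  if (any(nzchar(lab))) {
    df$label <- suppressWarnings(as.integer(lab))
  }
  as_corpus(df)
}

#' Write a corpus to CSV
#'
#' The written file round-trips through [read_citations()] byte-for-byte on
#' ids, titles and abstracts.
#'
#' @param corpus A `screen_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_citations <- function(corpus, path) {
  df <- as.data.frame(corpus)
  if (all(is.na(df$label))) df$label <- NULL
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Drop citations that have a title but no abstract
#'
#' Whitespace-only abstracts count as missing. The number of removed records
#' is reported via `message()`; removing everything raises a warning.
#'
#' @param corpus A `screen_corpus`.
#' @return Filtered `screen_corpus` (attributes such as `seeds` and
#'   `pos_lexicon` are preserved; seeds that were removed are dropped).
#' @export
filter_title_only <- function(corpus) {
  keep <- nzchar(trimws(corpus$abstract))
  removed <- sum(!keep)
  out <- corpus[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(corpus)
  if (removed > 0) {
    message(removed, " title-only citation(s) removed")
  }
  if (nrow(out) == 0L) {
    warning("all citations were title-only; corpus is empty")
  }
  seeds <- attr(corpus, "seeds")
  if (!is.null(seeds)) attr(out, "seeds") <- intersect(seeds, out$id)
  for (a in c("pos_lexicon", "theta", "synth_config")) {
    if (!is.null(attr(corpus, a))) attr(out, a) <- attr(corpus, a)
  }
  out
}

#' Combine title and abstract into the text used for screening
#'
#' The title and abstract are joined with a single space; a sentence
#' terminator `"."` is appended to the title first when it lacks one, so
#' sentence segmentation stays sane downstream.
#'
#' @param title,abstract Character vectors (recycled to a common length).
#' @return Character vector of combined screening texts.
#' @export
screening_text <- function(title, abstract) {
  if (any(!nzchar(trimws(abstract)))) {
    stop("screening_text requires a non-empty abstract; ",
         "apply filter_title_only() first")
  }
  title <- trimws(title)
  abstract <- trimws(abstract)
  no_term <- !grepl("[.!?]$", title)
  title[no_term] <- paste0(title[no_term], ".")
  paste(title, abstract)
}

#' @rdname screening_text
#' @param corpus A `screen_corpus`.
#' @return For `screening_texts()`: named character vector (names are ids).
#' @export
screening_texts <- function(corpus) {
  out <- screening_text(corpus$title, corpus$abstract)
  names(out) <- corpus$id
  out
}
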