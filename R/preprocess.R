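#' @useDynLib screenflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# irregular inflection -> lemma lookup; enough for common abstract English,
# the suffix rules below handle the regular cases
.irregular_lemmas <- c(
  ran = "run", runs = "run", running = "run",
  was = "be", were = "be", is = "be", are = "be", been = "be", being = "be",
  am = "be", has = "have", had = "have", having = "have",
  did = "do", does = "do", done = "do", doing = "do",
  went = "go", gone = "go", goes = "go", going = "go",
  found = "find", gave = "give", given = "give", took = "take",
  taken = "take", showed = "show", shown = "show", made = "make",
  bias = "bias", news = "news", diabetes = "diabetes", series = "series",
  mellitus = "mellitus", consensus = "consensus",
  mice = "mouse", men = "man", women = "woman", children = "child",
  feet = "foot", teeth = "tooth", data = "datum", criteria = "criterion",
  analyses = "analysis", hypotheses = "hypothesis", studies = "study",
  better = "good", best = "good", worse = "bad", worst = "bad",
  higher = "high", highest = "high", lower = "low", lowest = "low"
)

.vowel_re <- "[aeiou]"

lemmatize_word <- function(w) {
  hit <- .irregular_lemmas[w]
  if (!is.na(hit)) return(unname(hit))
  n <- nchar(w)
  # -ies -> -y (studies handled above, e.g. "therapies" -> "therapy")
  if (n > 4 && endsWith(w, "ies")) return(paste0(substr(w, 1, n - 3), "y"))
  if (n > 4 && (endsWith(w, "sses") || endsWith(w, "shes") ||
                endsWith(w, "ches") || endsWith(w, "xes") ||
                endsWith(w, "zes"))) {
    return(substr(w, 1, n - 2))
  }
  if (n > 3 && endsWith(w, "s") && !endsWith(w, "ss") && !endsWith(w, "us") &&
      !endsWith(w, "is")) {
    return(substr(w, 1, n - 1))
  }
  if (n > 5 && endsWith(w, "ing")) {
    stem <- substr(w, 1, n - 3)
    return(fix_stem(stem, w))
  }
  if (n > 4 && endsWith(w, "ed")) {
    stem <- substr(w, 1, n - 2)
    return(fix_stem(stem, w))
  }
  w
}

# undo consonant doubling ("running" -> "runn" -> "run") and restore a
# dropped final e ("dosed" -> "dos" -> "dose") when the stem looks truncated
fix_stem <- function(stem, original) {
  n <- nchar(stem)
  if (n < 3) return(original)
  last <- substr(stem, n, n)
  prev <- substr(stem, n - 1, n - 1)
  if (last == prev && !grepl(.vowel_re, last)) {
    return(substr(stem, 1, n - 1))
  }
  if (!grepl(paste0(.vowel_re, "$"), stem) &&
      grepl(paste0(.vowel_re, "[^aeiou]$"), stem) && n <= 4) {
    return(paste0(stem, "e"))
  }
  stem
}

lemmatize <- function(words) {
  vapply(words, lemmatize_word, "", USE.NAMES = FALSE)
}

# heuristic coarse tagger over {NOUN, VERB, ADJ, ADV, OTHER}; a lexicon of
# word -> tag (named character vector) takes precedence when supplied
.function_words <- c(
  "the", "a", "an", "and", "or", "but", "of", "in", "on", "at", "to", "for",
  "with", "by", "from", "as", "that", "this", "these", "those", "it", "its",
  "we", "our", "they", "their", "he", "she", "his", "her", "not", "no",
  "if", "than", "then", "so", "such", "per", "via", "be", "have", "do",
  "was", "were", "is", "are", "been", "can", "could", "may", "might",
  "will", "would", "shall", "should", "must", "about", "between", "among",
  "during", "after", "before", "into", "within", "without", "versus", "vs"
)

.common_verbs <- c(
  "run", "use", "show", "find", "include", "exclude", "assess", "evaluate",
  "compare", "report", "reduce", "increase", "decrease", "measure",
  "conduct", "perform", "identify", "screen", "treat", "improve",
  "associate", "randomize", "enrol", "enroll", "analyze", "analyse",
  "estimate", "observe", "predict", "review", "search", "select", "test",
  "examine", "determine", "suggest", "indicate", "demonstrate", "receive",
  "administer", "follow", "complete", "require"
)

pos_tag_word <- function(lemma, lexicon = NULL) {
  if (!is.null(lexicon)) {
    hit <- lexicon[lemma]
    if (!is.na(hit)) return(unname(hit))
  }
  if (lemma %in% .function_words) return("OTHER")
  if (lemma %in% .common_verbs) return("VERB")
  n <- nchar(lemma)
  if (n > 3 && endsWith(lemma, "ly")) return("ADV")
  if (n > 4 && (endsWith(lemma, "ize") || endsWith(lemma, "ise") ||
                endsWith(lemma, "ify") || endsWith(lemma, "ate"))) {
    return("VERB")
  }
  if (n > 4 && (endsWith(lemma, "ous") || endsWith(lemma, "ive") ||
                endsWith(lemma, "able") || endsWith(lemma, "ible") ||
                endsWith(lemma, "ical") || endsWith(lemma, "less") ||
                endsWith(lemma, "ful"))) {
    return("ADJ")
  }
  if (!grepl("^[a-z]", lemma)) return("OTHER")
  "NOUN"
}

#' Tokenize, lemmatize and POS-tag a screening text
#'
#' Sentences are split on `.`, `!` and `?`; tokens are maximal runs of
#' letters, digits, hyphens or apostrophes. Lemmas are lowercase normalized
#' forms obtained from an irregular-form table plus suffix-stripping rules;
#' POS tags are coarse (`NOUN`, `VERB`, `ADJ`, `ADV`, `OTHER`) and come from
#' the optional lexicon first, then suffix heuristics. Stop-words are kept
#' at this stage; per-stream filtering happens in [extract_streams()].
#'
#' @param text A single character string.
#' @param pos_lexicon Optional named character vector mapping lemma to tag,
#'   e.g. the lexicon attached to corpora from [generate_corpus()].
#' @return A `preproc_doc`: list with aligned `tokens`, `lemmas`, `pos` and
#'   `sentence` (integer sentence index per token).
#' @export
preprocess <- function(text, pos_lexicon = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  out <- list(tokens = character(), lemmas = character(),
              pos = character(), sentence = integer())
  class(out) <- "preproc_doc"
  if (is.na(text) || !nzchar(trimws(text))) return(out)
  sents <- strsplit(text, "[.!?]+", perl = TRUE)[[1]]
  sents <- sents[nzchar(trimws(sents))]
  toks <- list(); lems <- list(); tags <- list(); sid <- list()
  for (i in seq_along(sents)) {
    tk <- regmatches(sents[i],
                     gregexpr("[[:alnum:]][[:alnum:]'-]*", sents[i]))[[1]]
    if (!length(tk)) next
    lm <- lemmatize(tolower(tk))
    toks[[length(toks) + 1L]] <- tk
    lems[[length(lems) + 1L]] <- lm
    tags[[length(tags) + 1L]] <-
      vapply(lm, pos_tag_word, "", lexicon = pos_lexicon, USE.NAMES = FALSE)
    sid[[length(sid) + 1L]] <- rep.int(i, length(tk))
  }
  out$tokens <- unlist(toks, use.names = FALSE) %||% character()
  out$lemmas <- unlist(lems, use.names = FALSE) %||% character()
  out$pos <- unlist(tags, use.names = FALSE) %||% character()
  out$sentence <- unlist(sid, use.names = FALSE) %||% integer()
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default English stop-word list
#'
#' Read from the plain-text one-word-per-line file shipped under
#' `extdata/stopwords_en.txt`; a different list can be supplied anywhere a
#' `stopwords` argument appears.
#' @return Character vector of stop-words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "screenflow")
  readLines(path, warn = FALSE)
}

#' Extract the three token streams feeding the document representations
#'
#' From one preprocessed document, build (1) `ngrams`: all contiguous 1-,
#' 2- and 3-gram lemma strings within sentence boundaries, joined by `_`;
#' (2) `nouns_verbs`: lemmas tagged noun or verb; (3) `words`: alphabetic
#' lemmas. Numerals and single-character tokens are dropped everywhere.
#' Stop-words are removed from the `words` and `nouns_verbs` streams and
#' from the unigram part of `ngrams` only — interior stop-words of bigrams
#' and trigrams are kept (so phrases like `risk_of_bias` survive).
#'
#' @param doc A `preproc_doc` from [preprocess()].
#' @param stopwords Character vector; defaults to [default_stopwords()].
#' @return A list of three character vectors (multisets, with repeats):
#'   `ngrams`, `nouns_verbs`, `words`.
#' @export
extract_streams <- function(doc, stopwords = default_stopwords()) {
  stopifnot(inherits(doc, "preproc_doc"))
  keep <- nchar(doc$lemmas) >= 2 & grepl("[[:alpha:]]", doc$lemmas)
  lem <- doc$lemmas[keep]
  pos <- doc$pos[keep]
  sent <- doc$sentence[keep]
  is_stop <- lem %in% stopwords

  grams <- list(lem[!is_stop])
  for (s in unique(sent)) {
    lx <- lem[sent == s]
    L <- length(lx)
    if (L >= 2) {
      grams[[length(grams) + 1L]] <-
        paste(lx[-L], lx[-1], sep = "_")
    }
    if (L >= 3) {
      grams[[length(grams) + 1L]] <-
        paste(lx[1:(L - 2)], lx[2:(L - 1)], lx[3:L], sep = "_")
    }
  }
  list(
    ngrams = unlist(grams, use.names = FALSE),
    nouns_verbs = lem[pos %in% c("NOUN", "VERB") & !is_stop],
    words = lem[!is_stop]
  )
}

#' Preprocess a whole corpus into per-document token streams
#'
#' @param corpus A `screen_corpus` (already title-only filtered).
#' @param stopwords Stop-word vector.
#' @param pos_lexicon Optional lemma -> tag lexicon (see [preprocess()]).
#' @return Named list (by citation id) of stream lists as returned by
#'   [extract_streams()].
#' @export
corpus_streams <- function(corpus, stopwords = default_stopwords(),
                           pos_lexicon = attr(corpus, "pos_lexicon")) {
  texts <- screening_texts(corpus)
  out <- lapply(texts, function(tx) {
    extract_streams(preprocess(tx, pos_lexicon = pos_lexicon), stopwords)
  })
  names(out) <- corpus$id
  out
}
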