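#' Default English stopword list
#'
#' A compact Snowball-style English stopword list shipped with the package.
#' Entries are normalized the same way tokens are (lowercased, apostrophes
#' stripped) so they match cleaned tokens exactly.
#'
#' @return Character vector of stopword forms.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "emotopics",
                      mustWork = TRUE)
  normalize_wordlist(readLines(path, encoding = "UTF-8"))
}

#' Default lemma table
#'
#' A small word-form to lemma lookup table (e.g. "dogs" -> "dog"). Serious
#' analyses should supply a fuller table; lemmatization is table-driven so
#' that results are bit-for-bit reproducible.
#'
#' @return Named character vector mapping word forms to lemmas.
#' @export
default_lemma_table <- function() {
  path <- system.file("extdata", "lemmas_en.tsv", package = "emotopics",
                      mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  setNames(tab$lemma, tab$form)
}

normalize_wordlist <- function(x) {
  unique(gsub("['’]", "", tolower(x)))
}

# coerce a two-column data.frame or a named vector to a named lemma vector
as_lemma_map <- function(lemma_table) {
  if (is.null(lemma_table)) return(character(0))
  if (is.data.frame(lemma_table)) {
    stopifnot(ncol(lemma_table) >= 2)
    return(setNames(as.character(lemma_table[[2]]), as.character(lemma_table[[1]])))
  }
  if (is.null(names(lemma_table)) && length(lemma_table) > 0)
    stop("lemma_table must be a named vector (form -> lemma) or a two-column data.frame")
  lemma_table
}

# the mention placeholder must survive punctuation stripping
.mention_token <- "@user"
.mention_guard <- "zqzmentionzqz"

#' Clean and tokenize raw microblog text
#'
#' Applies, in this fixed order: (1) lowercase; (2) normalize every
#' user-mention token to the literal `"@user"`; (3) remove URLs; (4) remove
#' punctuation (apostrophes are deleted so "dog's" becomes "dogs", other
#' punctuation becomes a token boundary); (5) remove non-printable characters
#' and emoji; (6) whitespace tokenization; (7) stopword removal;
#' (8) table-driven lemmatization. The pipeline is deterministic and
#' idempotent on already-clean token text.
#'
#' @param raw_text Character scalar (any unicode input).
#' @param stopwords Character vector of stopword forms; defaults to the
#'   packaged list.
#' @param lemma_table Named character vector (form -> lemma) or two-column
#'   data.frame; defaults to the packaged table.
#' @return Character vector of normalized tokens (possibly empty).
#' @examples
#' clean_text("Dogs love @janedoe!!")
#' @export
clean_text <- function(raw_text, stopwords = default_stopwords(),
                       lemma_table = default_lemma_table()) {
  stopifnot(length(raw_text) == 1L)
  clean_text_vec(raw_text, stopwords, lemma_table)[[1L]]
}

# vectorized cleaning core; returns a list of token vectors
clean_text_vec <- function(x, stopwords = default_stopwords(),
                           lemma_table = default_lemma_table()) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  stopwords <- normalize_wordlist(stopwords)
  lemma_map <- as_lemma_map(lemma_table)

  x <- tolower(x)
  x <- gsub("@[a-z0-9_]+", .mention_token, x)
  x <- gsub("(https?://|www\\.)[^[:space:]]+", " ", x)
  x <- gsub(.mention_token, .mention_guard, x, fixed = TRUE)
  x <- gsub("['’]", "", x)          # apostrophes join: dog's -> dogs
  x <- gsub("[[:punct:]]+", " ", x)      # other punctuation splits
  x <- gsub("[[:cntrl:]]", " ", x)
  x <- gsub("[^ -~]", "", x)             # emoji / non-printable / non-ASCII
  tokens <- strsplit(trimws(x), "[[:space:]]+")
  lapply(tokens, function(tk) {
    tk <- tk[nzchar(tk)]
    tk <- tk[!(tk %in% stopwords)]
    hit <- match(tk, names(lemma_map))
    tk[!is.na(hit)] <- unname(lemma_map[hit[!is.na(hit)]])
    tk[tk == .mention_guard] <- .mention_token
    tk
  })
}

#' Clean every tweet in a corpus
#'
#' Populates the `tokens` list-column of the corpus by running [clean_text()]
#' on each tweet's raw text.
#'
#' @param corpus A `tweet_corpus`.
#' @inheritParams clean_text
#' @return The corpus with tokens filled in.
#' @export
clean_corpus <- function(corpus, stopwords = default_stopwords(),
                         lemma_table = default_lemma_table()) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  corpus$tweets$tokens <- clean_text_vec(corpus$tweets$text, stopwords, lemma_table)
  corpus
}
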