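#' Build a document-term matrix
#'
#' Tallies cleaned tokens into a sparse documents-by-vocabulary count matrix.
#' The vocabulary is sorted lexicographically for determinism; terms whose
#' total corpus count falls below `min_count` are dropped, so no all-zero
#' column remains.
#'
#' @param corpus A cleaned `tweet_corpus`, or a list of token vectors.
#' @param min_count Minimum total count for a term to be kept (default 1).
#' @return A `Matrix::dgCMatrix` with document ids as rownames and the
#'   vocabulary as colnames.
#' @export
build_dtm <- function(corpus, min_count = 1L) {
  if (inherits(corpus, "tweet_corpus")) {
    tokens <- corpus$tweets$tokens
    doc_ids <- corpus$tweets$tweet_id
  } else {
    tokens <- corpus
    doc_ids <- if (!is.null(names(tokens))) names(tokens) else
      paste0("doc", seq_along(tokens))
  }
  if (!length(tokens)) stop("empty corpus: no documents to tally")
  lens <- lengths(tokens)
  tok <- unlist(tokens, use.names = FALSE)
  if (!length(tok)) stop("empty corpus: no tokens present (clean the corpus first?)")
  vocab <- sort(unique(tok))
  m <- sparseMatrix(
    i = rep.int(seq_along(tokens), lens),
    j = match(tok, vocab),
    x = 1L,
    dims = c(length(tokens), length(vocab)),
    dimnames = list(doc_ids, vocab))
  m <- methods::as(m, "CsparseMatrix")
  if (min_count > 1L) {
    keep <- Matrix::colSums(m) >= min_count
    if (!any(keep)) stop("min_count removed the whole vocabulary")
    m <- m[, keep, drop = FALSE]
  }
  m
}

#' TF-IDF vocabulary filter
#'
#' Scores each term as the mean, over documents containing it, of
#' `count(d, t) / len(d) * log2(D / df(t))` and removes terms whose score is
#' at or below `threshold`. Documents emptied by the filtering are dropped
#' (with a message reporting how many).
#'
#' @param dtm Sparse document-term matrix from [build_dtm()].
#' @param threshold Nonnegative score cutoff (default 0.1).
#' @return Filtered dtm; the per-term scores of the retained vocabulary are
#'   attached as attribute `"tfidf"`.
#' @export
tfidf_filter <- function(dtm, threshold = 0.1) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("threshold must be a nonnegative number")
  scores <- tfidf_scores(dtm)
  keep <- !is.na(scores) & scores > threshold
  if (!any(keep)) stop("tfidf_filter removed the whole vocabulary")
  out <- dtm[, keep, drop = FALSE]
  emptied <- Matrix::rowSums(out) == 0 & Matrix::rowSums(dtm) > 0
  if (any(emptied)) {
    message(sum(emptied), " document(s) emptied by TF-IDF filtering were dropped")
    out <- out[!emptied, , drop = FALSE]
  }
  attr(out, "tfidf") <- scores[keep]
  out
}

#' Per-term TF-IDF scores
#'
#' @param dtm Sparse document-term matrix.
#' @return Named numeric vector: mean TF-IDF over the documents containing
#'   each term (`NA` for a term present in no document).
#' @export
tfidf_scores <- function(dtm) {
  dtm <- methods::as(dtm, "CsparseMatrix")
  D <- nrow(dtm)
  len <- Matrix::rowSums(dtm)
  df <- Matrix::colSums(dtm > 0)
  tf <- Matrix::Diagonal(x = ifelse(len == 0, 0, 1 / len)) %*% dtm
  idf <- log2(D / df)
  score <- (Matrix::colSums(tf) / ifelse(df == 0, NA_real_, df)) * idf
  setNames(as.numeric(score), colnames(dtm))
}
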