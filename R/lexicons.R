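#' Build an emotion lexicon object
#'
#' @param associations Named list mapping a word to the character vector of
#'   categories it is associated with. Category names must come from
#'   [emotion_categories()].
#' @return An `emotion_lexicon`: a named list of category vectors with
#'   lowercase word keys.
#' @export
emotion_lexicon <- function(associations = list()) {
  if (length(associations)) {
    names(associations) <- tolower(names(associations))
    bad <- setdiff(unique(unlist(associations)), emotion_categories())
    if (length(bad))
      stop("unknown emotion category: ", paste(bad, collapse = ", "))
    associations <- lapply(associations, function(x) sort(unique(x)))
    associations <- associations[lengths(associations) > 0]
  }
  structure(associations, class = "emotion_lexicon")
}

#' @exportS3Method base::print
print.emotion_lexicon <- function(x, ...) {
  cat(sprintf("emotion_lexicon: %d words, %d associations over %d categories\n",
              length(x), sum(lengths(x)), length(emotion_categories())))
  invisible(x)
}

# long (word, category) view used by the vectorized scorers
emotion_lexicon_long <- function(lexicon) {
  if (!length(lexicon))
    return(data.frame(word = character(0), category = character(0)))
  data.frame(word = rep(names(lexicon), lengths(lexicon)),
             category = unlist(lexicon, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Load an EmoLex-format emotion lexicon
#'
#' Flat format: one `word<TAB>category<TAB>flag` association per line, flag in
#' \{0, 1\}. Only flag-1 lines create associations; a word whose flags are all
#' zero is absent from the lexicon. Conflicting duplicate lines (same word and
#' category, different flags) are a format error.
#'
#' @param path Path to the flat file.
#' @return An [emotion_lexicon()].
#' @export
load_emotion_lexicon <- function(path) {
  if (!file.exists(path)) stop("emotion lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(emotion_lexicon())
  parts <- strsplit(lines, "[\t ]+")
  nf <- lengths(parts)
  if (any(nf != 3))
    stop("malformed emotion lexicon line (expected word, category, flag): ",
         lines[which(nf != 3)[1]])
  word <- tolower(vapply(parts, `[`, character(1), 1L))
  category <- vapply(parts, `[`, character(1), 2L)
  flag_chr <- vapply(parts, `[`, character(1), 3L)
  bad_cat <- setdiff(unique(category), emotion_categories())
  if (length(bad_cat))
    stop("unknown emotion category: ", paste(bad_cat, collapse = ", "))
  if (!all(flag_chr %in% c("0", "1")))
    stop("non-binary association flag: ",
         flag_chr[which(!flag_chr %in% c("0", "1"))[1]])
  flag <- as.integer(flag_chr)
  key <- paste(word, category, sep = "\r")
  conflict <- tapply(flag, key, function(f) length(unique(f)) > 1)
  if (any(conflict))
    stop("conflicting duplicate association for: ",
         sub("\r", " / ", names(conflict)[which(conflict)[1]]))
  keep <- !duplicated(key) & flag == 1L
  emotion_lexicon(split(category[keep], word[keep]))
}

#' Write an emotion lexicon in EmoLex flat format
#'
#' Emits all 10 categories per word with 0/1 flags so the file is a faithful
#' round-trip partner of [load_emotion_lexicon()].
#'
#' @param lexicon An `emotion_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_emotion_lexicon <- function(lexicon, path) {
  cats <- emotion_categories()
  words <- sort(names(lexicon))
  lines <- unlist(lapply(words, function(w) {
    paste(w, cats, as.integer(cats %in% lexicon[[w]]), sep = "\t")
  }))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Build a happiness lexicon object
#'
#' @param scores Named numeric vector of word happiness scores; every score
#'   must lie in \[1, 9\] (labMT scale).
#' @return A `happiness_lexicon`: named numeric vector with lowercase keys.
#' @export
happiness_lexicon <- function(scores = numeric(0)) {
  if (length(scores)) {
    names(scores) <- tolower(names(scores))
    out_of_range <- names(scores)[scores < 1 | scores > 9 | is.na(scores)]
    if (length(out_of_range))
      stop("happiness score outside [1, 9] for word(s): ",
           paste(head(out_of_range, 5), collapse = ", "))
  }
  structure(scores, class = "happiness_lexicon")
}

#' @exportS3Method base::print
print.happiness_lexicon <- function(x, ...) {
  cat(sprintf("happiness_lexicon: %d words, scores in [%.2f, %.2f]\n",
              length(x), if (length(x)) min(x) else NA, if (length(x)) max(x) else NA))
  invisible(x)
}

#' Load a labMT-style happiness lexicon
#'
#' Accepts a delimited file with at least (word, mean happiness) columns.
#' With a header, columns named `word` and one matching `happ|mean|score` are
#' used; without one, a 2-column file is read as (word, mean) and a wider
#' file as the classic labMT layout (word, rank, mean, sd).
#'
#' @param path Path to the delimited file.
#' @return A [happiness_lexicon()].
#' @export
load_happiness_lexicon <- function(path) {
  if (!file.exists(path)) stop("happiness lexicon file not found: ", path)
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  if (!length(first) || !nzchar(trimws(first))) return(happiness_lexicon())
  fields <- strsplit(trimws(first), "[\t ]+")[[1]]
  has_header <- length(fields) >= 2 && all(is.na(suppressWarnings(as.numeric(fields[-1]))))
  tab <- read.table(path, header = has_header, sep = "", fill = TRUE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  if (has_header) {
    nm <- tolower(names(tab))
    wcol <- if (any(nm == "word")) which(nm == "word")[1] else 1L
    scol <- grep("happ|mean|score", nm)
    scol <- setdiff(scol, grep("sd|std|dev|rank", nm))
    scol <- if (length(scol)) scol[1] else 2L
  } else {
    wcol <- 1L
    scol <- if (ncol(tab) >= 3) 3L else 2L
  }
  word <- tolower(as.character(tab[[wcol]]))
  score <- suppressWarnings(as.numeric(tab[[scol]]))
  if (anyNA(score))
    stop("non-numeric happiness score for word(s): ",
         paste(head(word[is.na(score)], 5), collapse = ", "))
  happiness_lexicon(setNames(score, word))
}

#' Write a happiness lexicon in labMT-like format
#'
#' @param lexicon A `happiness_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_happiness_lexicon <- function(lexicon, path) {
  ord <- order(-unclass(lexicon))
  tab <- data.frame(word = names(lexicon)[ord],
                    rank = seq_along(lexicon),
                    happiness_average = as.numeric(lexicon)[ord],
                    happiness_sd = 0)
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up happiness scores for words
#'
#' Case-insensitive lookup; unmatched words yield `NA`.
#'
#' @param lexicon A `happiness_lexicon`.
#' @param words Character vector.
#' @return Numeric vector of scores aligned to `words`.
#' @export
happiness_score <- function(lexicon, words) {
  stopifnot(inherits(lexicon, "happiness_lexicon"))
  unname(unclass(lexicon)[tolower(words)])
}
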