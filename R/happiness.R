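#' Happiness score of a tweet
#'
#' Frequency-weighted mean of the lexicon happiness scores of the tweet's
#' tokens. With `lens_delta > 0`, words whose score lies strictly inside
#' `(5 - lens_delta, 5 + lens_delta)` are excluded first (the hedonometer
#' "lens" that drops emotionally neutral words). Missing when no token
#' survives.
#'
#' @param tokens Cleaned token vector.
#' @param lexicon A `happiness_lexicon`.
#' @param lens_delta Nonnegative half-width of the neutral exclusion band
#'   (default 0 = no exclusion). Must be < 4.
#' @return Numeric scalar in \[1, 9\], or `NA`.
#' @export
tweet_happiness <- function(tokens, lexicon, lens_delta = 0) {
  check_lens(lens_delta)
  h <- happiness_score(lexicon, tokens)
  h <- h[!is.na(h)]
  if (lens_delta > 0) h <- h[h <= 5 - lens_delta | h >= 5 + lens_delta]
  if (!length(h)) return(NA_real_)
  mean(h)
}

check_lens <- function(lens_delta) {
  if (!is.numeric(lens_delta) || length(lens_delta) != 1L || lens_delta < 0 ||
      lens_delta >= 4)
    stop("lens_delta must be in [0, 4): values >= 4 would exclude the whole scale interior")
  invisible(lens_delta)
}

#' Daily mean happiness series by gender
#'
#' For each UTC calendar day and gender, pools all lexicon-matched word
#' scores across that day's tweets (word-level pooling, not a mean of tweet
#' means) and returns their mean with the contributing word count. With
#' `per_user = TRUE`, scores are first averaged within each user's day and
#' the user means are then averaged.
#'
#' @param corpus Cleaned, gendered `tweet_corpus`.
#' @param lexicon A `happiness_lexicon`.
#' @param lens_delta See [tweet_happiness()].
#' @param per_user Average per user first (default FALSE = direct pooling).
#' @return Tibble: date ("YYYY-MM-DD"), gender, mean, n_words.
#' @export
daily_series <- function(corpus, lexicon, lens_delta = 0, per_user = FALSE) {
  check_lens(lens_delta)
  tw <- corpus$tweets
  lens <- lengths(tw$tokens)
  d <- tibble(
    word = unlist(tw$tokens, use.names = FALSE),
    date = rep(format(tw$timestamp, "%Y-%m-%d", tz = "UTC"), lens),
    user_id = rep(tw$user_id, lens)
  )
  d$gender <- corpus$users$gender[match(d$user_id, corpus$users$user_id)]
  d$h <- happiness_score(lexicon, d$word)
  d <- d[!is.na(d$h), ]
  if (lens_delta > 0) d <- d[d$h <= 5 - lens_delta | d$h >= 5 + lens_delta, ]
  if (!nrow(d))
    return(tibble(date = character(0), gender = character(0),
                  mean = numeric(0), n_words = integer(0)))
  if (per_user) {
    by_user <- dplyr::summarise(
      dplyr::group_by(d, .data$date, .data$gender, .data$user_id),
      mean = mean(.data$h), n_words = dplyr::n(), .groups = "drop")
    out <- dplyr::summarise(
      dplyr::group_by(by_user, .data$date, .data$gender),
      mean = mean(.data$mean), n_words = sum(.data$n_words), .groups = "drop")
  } else {
    out <- dplyr::summarise(
      dplyr::group_by(d, .data$date, .data$gender),
      mean = mean(.data$h), n_words = dplyr::n(), .groups = "drop")
  }
  dplyr::arrange(out, .data$date, .data$gender)
}

#' Happiness summary of a word set
#'
#' Unweighted mean and sample standard deviation over the words found in
#' the lexicon; unmatched words are skipped and counted.
#'
#' @param words Character vector.
#' @param lexicon A `happiness_lexicon`.
#' @return List with `mean`, `sd`, `n` (matched count) and `n_unmatched`.
#'   `mean`/`sd` are `NA` when no word matches; `sd` is 0 for a single match.
#' @export
set_happiness <- function(words, lexicon) {
  h <- happiness_score(lexicon, words)
  matched <- h[!is.na(h)]
  n <- length(matched)
  list(
    mean = if (n) mean(matched) else NA_real_,
    sd = if (n == 0) NA_real_ else if (n == 1) 0 else sd(matched),
    n = n,
    n_unmatched = length(words) - n
  )
}
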