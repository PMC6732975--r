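#' Count emotion-lexicon words in a token sequence
#'
#' Each token adds 1 to every category its form is associated with; tokens
#' absent from the lexicon contribute nothing. The result does not depend on
#' token order.
#'
#' @param tokens Character vector of cleaned tokens.
#' @param lexicon An `emotion_lexicon`.
#' @return Named integer vector over the 10 fixed categories.
#' @export
score_emotions <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "emotion_lexicon"))
  cats <- emotion_categories()
  out <- setNames(integer(length(cats)), cats)
  if (!length(tokens)) return(out)
  hit <- tokens[tokens %in% names(lexicon)]
  if (!length(hit)) return(out)
  tab <- table(factor(unlist(unclass(lexicon)[hit], use.names = FALSE),
                      levels = cats))
  out[] <- as.integer(tab)
  out
}

# tweets x 10 count matrix for a whole corpus (vectorized)
corpus_emotion_counts <- function(corpus, lexicon) {
  cats <- emotion_categories()
  n <- nrow(corpus$tweets)
  tokens <- corpus$tweets$tokens
  lens <- lengths(tokens)
  tok <- unlist(tokens, use.names = FALSE)
  idx <- rep.int(seq_len(n), lens)
  keep <- tok %in% names(lexicon)
  counts <- matrix(0L, n, length(cats), dimnames = list(NULL, cats))
  if (any(keep)) {
    cat_list <- unclass(lexicon)[tok[keep]]
    tab <- table(factor(rep.int(idx[keep], lengths(cat_list)), levels = seq_len(n)),
                 factor(unlist(cat_list, use.names = FALSE), levels = cats))
    counts[] <- as.integer(tab)
  }
  counts
}

#' Per-tweet emotion proportion
#'
#' The proportion of emotion-X words relative to the tweet's total
#' sentiment-bearing words: `count(X) / (count(negative) + count(positive))`.
#' Undefined (NA) when the tweet contains no positive- or negative-labelled
#' words. For X in \{positive, negative\} the value lies in \[0, 1\] and the
#' two proportions sum to 1 whenever defined.
#'
#' @param counts Named count vector from [score_emotions()].
#' @param emotion One of [emotion_categories()].
#' @return Numeric scalar, or `NA` when undefined.
#' @export
emotion_proportion <- function(counts, emotion) {
  if (!emotion %in% emotion_categories())
    stop("unknown emotion category: ", emotion)
  denom <- counts[["negative"]] + counts[["positive"]]
  if (denom == 0) return(NA_real_)
  counts[[emotion]] / denom
}

#' Percentage breakdown of category counts
#'
#' Each category's share of the 10-category total, in percent.
#'
#' @param counts Named nonnegative vector over the 10 categories.
#' @param digits Decimals to round to (default 1, the reporting convention).
#' @return Named numeric vector of percentages (NA when the total is 0).
#' @export
emotion_percentages <- function(counts, digits = 1) {
  total <- sum(counts)
  if (total == 0) return(setNames(rep(NA_real_, length(counts)), names(counts)))
  round(100 * counts / total, digits)
}

#' Raw emotion word counts and shares by gender
#'
#' Sums per-tweet emotion counts within each gender and expresses each
#' category as a percentage of that gender's 10-category total.
#'
#' @param corpus Cleaned `tweet_corpus` with gendered users.
#' @param lexicon An `emotion_lexicon`.
#' @return Tibble with columns gender, category, count, pct.
#' @export
build_emotion_table <- function(corpus, lexicon) {
  counts <- corpus_emotion_counts(corpus, lexicon)
  gender <- corpus$users$gender[match(corpus$tweets$user_id, corpus$users$user_id)]
  out <- lapply(c("woman", "man"), function(g) {
    sel <- gender == g
    tot <- if (any(sel)) colSums(counts[sel, , drop = FALSE]) else
      setNames(numeric(ncol(counts)), colnames(counts))
    tibble(gender = g, category = names(tot), count = as.numeric(tot),
           pct = emotion_percentages(tot))
  })
  dplyr::bind_rows(out)
}

#' Variance-ratio (F) test
#'
#' `F = var(x) / var(y)` with sample variances (denominator n - 1) and a
#' two-sided p-value from the F distribution with `(n_x - 1, n_y - 1)`
#' degrees of freedom. Used to check variance homogeneity before the
#' rank-sum comparison.
#'
#' @param x,y Numeric samples with at least 2 values each.
#' @return List with `statistic`, `df` (length-2), `p_value`.
#' @export
variance_ratio_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("both samples need at least 2 values")
  vy <- var(y)
  if (vy == 0) stop("degenerate sample: var(y) = 0")
  f <- var(x) / vy
  df <- c(length(x) - 1L, length(y) - 1L)
  lower <- pf(f, df[1], df[2])
  p <- min(1, 2 * min(lower, 1 - lower))
  list(statistic = f, df = df, p_value = p)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' `W` is the Mann-Whitney U statistic: the number of pairs `(i, j)` with
#' `x_i > y_j` plus half the tied pairs. The two-sided p-value uses the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Nonempty numeric samples.
#' @return List with `statistic` (W), `p_value`.
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) stop("both samples must be nonempty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  nties <- table(r)
  mu <- n * m / 2
  sigma2 <- (n * m / 12) *
    ((n + m + 1) - sum(nties^3 - nties) / ((n + m) * (n + m - 1)))
  if (sigma2 <= 0) return(list(statistic = w, p_value = 1))
  z <- w - mu
  corr <- sign(z) * 0.5
  z <- (z - corr) / sqrt(sigma2)
  list(statistic = w, p_value = min(1, 2 * pnorm(-abs(z))))
}

# per-tweet proportions for a set of emotions, with gender and month attached
corpus_emotion_proportions <- function(corpus, lexicon,
                                       emotions = emotion_categories()) {
  counts <- corpus_emotion_counts(corpus, lexicon)
  denom <- counts[, "negative"] + counts[, "positive"]
  gender <- corpus$users$gender[match(corpus$tweets$user_id, corpus$users$user_id)]
  props <- counts[, emotions, drop = FALSE] / ifelse(denom == 0, NA_real_, denom)
  tibble(
    tweet_id = rep(corpus$tweets$tweet_id, times = length(emotions)),
    gender = rep(gender, times = length(emotions)),
    timestamp = rep(corpus$tweets$timestamp, times = length(emotions)),
    emotion = rep(emotions, each = nrow(counts)),
    proportion = as.numeric(props)
  )
}

#' Gender comparison of per-tweet emotion proportions
#'
#' For each emotion, pools the per-tweet proportion statistic by gender
#' (tweets with undefined proportion excluded), then applies the
#' variance-ratio test and the rank-sum test (women as the first sample).
#'
#' @param corpus Cleaned, gendered `tweet_corpus`.
#' @param lexicon An `emotion_lexicon`.
#' @param emotions Character vector of categories (default all 10).
#' @return Tibble: one row per emotion with medians/means per gender, F with
#'   degrees of freedom and p, W and p, sample sizes, and an `untestable`
#'   flag for emotions where a gender has no defined proportions.
#' @export
compare_groups <- function(corpus, lexicon, emotions = emotion_categories()) {
  props <- corpus_emotion_proportions(corpus, lexicon, emotions)
  rows <- lapply(emotions, function(e) {
    sub <- props[props$emotion == e & !is.na(props$proportion), ]
    xw <- sub$proportion[sub$gender == "woman"]
    xm <- sub$proportion[sub$gender == "man"]
    base <- tibble(
      emotion = e,
      n_women = length(xw), n_men = length(xm),
      median_women = if (length(xw)) median(xw) else NA_real_,
      mean_women = if (length(xw)) mean(xw) else NA_real_,
      median_men = if (length(xm)) median(xm) else NA_real_,
      mean_men = if (length(xm)) mean(xm) else NA_real_
    )
    if (length(xw) < 2 || length(xm) < 2) {
      return(dplyr::mutate(base, F = NA_real_, df1 = NA_integer_,
                           df2 = NA_integer_, p_f = NA_real_, W = NA_real_,
                           p_w = NA_real_, untestable = TRUE))
    }
    ft <- tryCatch(variance_ratio_test(xw, xm), error = function(e2) NULL)
    rt <- rank_sum_test(xw, xm)
    dplyr::mutate(base,
      F = if (is.null(ft)) NA_real_ else ft$statistic,
      df1 = if (is.null(ft)) NA_integer_ else ft$df[1],
      df2 = if (is.null(ft)) NA_integer_ else ft$df[2],
      p_f = if (is.null(ft)) NA_real_ else ft$p_value,
      W = rt$statistic, p_w = rt$p_value,
      untestable = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Monthly mean emotion-proportion series by gender
#'
#' Means of the defined per-tweet proportions grouped by UTC calendar month
#' and gender; month/gender cells with no defined values are absent.
#'
#' @inheritParams compare_groups
#' @return Tibble: month ("YYYY-MM"), gender, emotion, mean, n.
#' @export
monthly_series <- function(corpus, lexicon, emotions = emotion_categories()) {
  props <- corpus_emotion_proportions(corpus, lexicon, emotions)
  props <- props[!is.na(props$proportion), ]
  props$month <- format(props$timestamp, "%Y-%m", tz = "UTC")
  out <- dplyr::summarise(
    dplyr::group_by(props, .data$month, .data$gender, .data$emotion),
    mean = mean(.data$proportion), n = dplyr::n(), .groups = "drop")
  dplyr::arrange(out, .data$month, .data$gender, .data$emotion)
}
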