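#' Select users by Twitter-list membership
#'
#' Keeps exactly the users appearing in at least `min_lists` distinct lists —
#' the cohort inclusion rule (membership in several topic-specific lists marks
#' a user as belonging to the community of interest).
#'
#' @param memberships Named list mapping user id to a vector of list
#'   identifiers (may be empty).
#' @param min_lists Positive integer threshold (default 3).
#' @return Character vector of selected user ids, in input order.
#' @export
select_members <- function(memberships, min_lists = 3L) {
  if (is.null(memberships)) stop("memberships must be non-null")
  if (!is.numeric(min_lists) || length(min_lists) != 1L || min_lists < 1)
    stop("min_lists must be a positive integer")
  if (!length(memberships)) return(character(0))
  n_lists <- vapply(memberships, function(x) length(unique(x)), integer(1))
  names(memberships)[n_lists >= min_lists]
}

#' Cohort summary arithmetic from user-level counts
#'
#' Computes the per-gender and overall sample-description summaries from a
#' user table and per-user collected-tweet counts. Users with unknown gender
#' are excluded from the gender-stratified rows but counted in overall totals.
#'
#' @param users Tibble with `user_id`, `gender`, `lifetime_tweet_count`,
#'   `follower_count` and optionally `country`.
#' @param collected_counts Named integer vector: collected tweets per user id.
#' @param round_fraction Decimals for collected-fraction percentages (default 1).
#' @param round_geo Decimals for geolocation/country percentages (default 2).
#' @return A `cohort_summary`: list with `per_gender` and `overall` elements.
#' @export
cohort_summary <- function(users, collected_counts, round_fraction = 1,
                           round_geo = 2) {
  users <- as_tibble(users)
  if (!"country" %in% names(users)) users$country <- NA_character_
  if (!"follower_count" %in% names(users)) users$follower_count <- 0L
  collected <- unname(collected_counts[users$user_id])
  collected[is.na(collected)] <- 0L

  one_gender <- function(g) {
    sel <- users$gender == g
    n <- sum(sel)
    if (n == 0) {
      return(tibble(gender = g, n_users = 0L, collected_tweets = 0L,
                    lifetime_tweets = 0L, mean_tweets_per_user = NA_real_,
                    pct_over_500 = NA_real_, pct_over_1000 = NA_real_,
                    follower_total = 0L, collected_fraction_pct = NA_real_))
    }
    col <- sum(collected[sel])
    life <- sum(users$lifetime_tweet_count[sel])
    tibble(
      gender = g,
      n_users = n,
      collected_tweets = col,
      lifetime_tweets = life,
      mean_tweets_per_user = round(col / n),
      pct_over_500 = round(100 * mean(collected[sel] > 500)),
      pct_over_1000 = round(100 * mean(collected[sel] > 1000)),
      follower_total = sum(users$follower_count[sel]),
      collected_fraction_pct = if (life > 0) round(100 * col / life, round_fraction) else NA_real_
    )
  }
  per_gender <- dplyr::bind_rows(lapply(c("woman", "man"), one_gender))

  total_collected <- sum(collected)
  total_lifetime <- sum(users$lifetime_tweet_count)
  geo <- !is.na(users$country) & nzchar(users$country)
  country_tab <- if (any(geo)) {
    tab <- sort(table(users$country[geo]), decreasing = TRUE)
    tibble(country = names(tab), n_users = as.integer(tab),
           pct = round(100 * as.integer(tab) / sum(geo), round_geo))
  } else {
    tibble(country = character(0), n_users = integer(0), pct = numeric(0))
  }
  overall <- list(
    n_users = nrow(users),
    collected_tweets = total_collected,
    lifetime_tweets = total_lifetime,
    collected_fraction_pct = if (total_lifetime > 0)
      round(100 * total_collected / total_lifetime, round_fraction) else NA_real_,
    geolocated_users = sum(geo),
    geolocated_pct = round(100 * sum(geo) / nrow(users), round_geo),
    countries = country_tab
  )
  structure(list(per_gender = per_gender, overall = overall),
            class = "cohort_summary")
}

#' @exportS3Method base::print
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort_summary: %d users, %d collected of %d lifetime tweets (%.1f%%)\n",
              x$overall$n_users, x$overall$collected_tweets,
              x$overall$lifetime_tweets, x$overall$collected_fraction_pct))
  print(x$per_gender)
  invisible(x)
}

#' Summarize a corpus cohort
#'
#' Counts each user's collected tweets in the corpus and delegates to
#' [cohort_summary()].
#'
#' @param corpus A `tweet_corpus` whose users carry gender and lifetime counts.
#' @inheritParams cohort_summary
#' @return A `cohort_summary`.
#' @export
summarize_cohort <- function(corpus, round_fraction = 1, round_geo = 2) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  counts <- table(factor(corpus$tweets$user_id, levels = corpus$users$user_id))
  cohort_summary(corpus$users, setNames(as.integer(counts), names(counts)),
                 round_fraction = round_fraction, round_geo = round_geo)
}
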