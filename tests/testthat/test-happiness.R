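toy_hap <- function() happiness_lexicon(c(love = 8.42, happy = 8.3, a = 2,
                                          b = 8, mid = 5, low = 1.5))

test_that("tweet happiness is the frequency-weighted mean of matched words", {
  lex <- toy_hap()
  expect_equal(tweet_happiness("love", lex), 8.42)
  expect_equal(tweet_happiness(c("a", "b"), lex), 5.0)
  expect_equal(tweet_happiness(c("a", "a", "b"), lex), 4.0)
  expect_true(is.na(tweet_happiness(c("zz", "yy"), lex)))
  expect_true(is.na(tweet_happiness(character(0), lex)))
})

test_that("the neutral lens excludes mid-scale words and validates its width", {
  lex <- toy_hap()
  expect_equal(tweet_happiness(c("mid", "b"), lex, lens_delta = 1), 8)
  expect_true(is.na(tweet_happiness("mid", lex, lens_delta = 1)))
  # boundary words (|h - 5| == delta) are kept
  expect_equal(tweet_happiness(c("mid", "b"), lex, lens_delta = 0), 6.5)
  expect_error(tweet_happiness("mid", lex, lens_delta = 4), "lens_delta")
})

test_that("happiness is invariant under duplicating the token list and bounded", {
  lex <- toy_hap()
  set.seed(41)
  for (i in 1:20) {
    toks <- sample(names(unclass(lex)), sample(1:8, 1), replace = TRUE)
    h <- tweet_happiness(toks, lex)
    expect_equal(tweet_happiness(c(toks, toks), lex), h)
    scores <- happiness_score(lex, toks)
    expect_gte(h, min(scores)); expect_lte(h, max(scores))
  }
})

test_that("daily series pools at word level, not tweet level", {
  lex <- toy_hap()
  # same day: tweet 1 has 1 matched word (h=2), tweet 2 has 3 (8, 8, 5)
  corp <- make_corpus(list(c("a"), c("b", "b", "mid")),
                      c("woman", "woman"), rep("2018-02-03", 2))
  d <- daily_series(corp, lex)
  expect_equal(nrow(d), 1L)
  expect_equal(d$mean, (2 + 8 + 8 + 5) / 4)   # word pooling
  expect_false(isTRUE(all.equal(d$mean, mean(c(2, 7)))))  # not mean of tweet means
  expect_equal(d$n_words, 4L)
  # per-user variant averages users within the day
  corp2 <- make_corpus(list(c("a"), c("b", "b", "mid")),
                       c("woman", "woman"), rep("2018-02-03", 2))
  du <- daily_series(corp2, lex, per_user = TRUE)
  expect_equal(du$mean, mean(c(2, 7)))
})

test_that("daily series equals a brute-force (day, gender) group-by", {
  g <- generate_corpus(synthetic_config(n_users = 10, tweets_per_user = 8,
                                        date_start = "2018-05-01",
                                        date_end = "2018-05-10", seed = 23))
  d <- daily_series(g$corpus, g$happiness_lexicon)
  gender <- g$corpus$users$gender[match(g$corpus$tweets$user_id,
                                        g$corpus$users$user_id)]
  day <- format(g$corpus$tweets$timestamp, "%Y-%m-%d", tz = "UTC")
  for (r in seq_len(nrow(d))) {
    idx <- which(day == d$date[r] & gender == d$gender[r])
    scores <- unlist(lapply(idx, function(i)
      happiness_score(g$happiness_lexicon, g$corpus$tweets$tokens[[i]])))
    scores <- scores[!is.na(scores)]
    expect_equal(d$mean[r], mean(scores))
    expect_equal(d$n_words[r], length(scores))
  }
})

test_that("set happiness averages matched words and counts misses", {
  lex <- toy_hap()
  s <- set_happiness(c("love", "happy"), lex)
  expect_equal(s$mean, 8.36)
  expect_equal(s$n, 2L)
  expect_equal(set_happiness("love", lex)$sd, 0)
  s0 <- set_happiness(c("nope", "nada"), lex)
  expect_true(is.na(s0$mean)); expect_equal(s0$n, 0L)
  expect_equal(s0$n_unmatched, 2L)
  s2 <- set_happiness(c("a", "b", "ghost"), lex)
  expect_equal(s2$mean, 5); expect_equal(s2$sd, stats::sd(c(2, 8)))
  expect_equal(s2$n_unmatched, 1L)
})

test_that("planted happiness gap makes women dominate almost every day", {
  em <- null_emission()
  em["woman", ] <- em["man", ] <-
    c(anger = .02, anticipation = .04, disgust = .02, fear = .03, joy = .05,
      sadness = .03, surprise = .02, trust = .05, negative = .05,
      positive = .05)[emotion_categories()]
  em["woman", "positive"] <- 0.15   # women's emitted-word mean ~0.4 higher
  em["man", "negative"] <- 0.15
  g <- generate_corpus(synthetic_config(
    n_users = 50, tweets_per_user = 40, date_start = "2018-01-01",
    date_end = "2018-01-31", emission = em, seed = 9))
  d <- daily_series(g$corpus, g$happiness_lexicon)
  expect_gte(min(d$n_words), 200)
  wide <- merge(d[d$gender == "woman", c("date", "mean")],
                d[d$gender == "man", c("date", "mean")], by = "date")
  expect_gte(mean(wide$mean.x > wide$mean.y), 0.9)
})
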