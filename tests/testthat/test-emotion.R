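test_that("score_emotions counts category hits, order-invariantly", {
  lex <- toy_emotion_lexicon()
  zero <- score_emotions(character(0), lex)
  expect_true(all(zero == 0L))
  counts <- score_emotions(c("good", "good", "bad"), lex)
  expect_equal(counts[["joy"]], 2L)
  expect_equal(counts[["positive"]], 2L)
  expect_equal(counts[["sadness"]], 1L)
  expect_equal(counts[["negative"]], 1L)
  expect_equal(sum(counts), 6L)
  toks <- c("good", "odd", "bad", "unknownword", "calm", "good")
  expect_equal(score_emotions(toks, lex), score_emotions(rev(toks), lex))
})

test_that("score_emotions matches the brute-force oracle on random inputs", {
  lex <- toy_emotion_lexicon()
  set.seed(21)
  pool <- c(names(lex), paste0("x", 1:10))
  for (i in 1:25) {
    toks <- sample(pool, sample(0:30, 1), replace = TRUE)
    expect_equal(score_emotions(toks, lex), brute_score_emotions(toks, lex))
  }
})

test_that("emotion proportion follows the sentiment-denominator formula", {
  lex <- toy_emotion_lexicon()
  c1 <- score_emotions(c("good", "bad"), lex)  # joy=1, pos=1, neg=1... denom=2
  expect_equal(emotion_proportion(c1, "joy"), 0.5)
  c2 <- score_emotions(c("good", "calm", "bad"), lex)  # pos=2, neg=1
  expect_equal(emotion_proportion(c2, "positive"), 2 / 3)
  expect_equal(emotion_proportion(c2, "negative"), 1 / 3)
  expect_equal(emotion_proportion(c2, "positive") +
                 emotion_proportion(c2, "negative"), 1)
  c3 <- score_emotions(c("odd", "zzz"), lex)   # no sentiment words
  expect_true(is.na(emotion_proportion(c3, "joy")))
  expect_error(emotion_proportion(c1, "bliss"), "unknown emotion")
})

test_that("positive and negative proportions sum to 1 on every defined tweet", {
  g <- generate_corpus(synthetic_config(n_users = 15, tweets_per_user = 10,
                                        seed = 3))
  counts <- lapply(g$corpus$tweets$tokens, score_emotions, lexicon = g$emotion_lexicon)
  sums <- vapply(counts, function(ct) {
    p <- emotion_proportion(ct, "positive")
    if (is.na(p)) return(NA_real_)
    p + emotion_proportion(ct, "negative")
  }, numeric(1))
  defined <- sums[!is.na(sums)]
  expect_gt(length(defined), 50)
  expect_true(all(abs(defined - 1) < 1e-12))
})

test_that("emotion table counts conserve per-tweet scores and percentages sum to 100", {
  g <- generate_corpus(synthetic_config(n_users = 10, tweets_per_user = 8,
                                        seed = 8))
  tab <- build_emotion_table(g$corpus, g$emotion_lexicon)
  gender <- g$corpus$users$gender[match(g$corpus$tweets$user_id,
                                        g$corpus$users$user_id)]
  for (gg in c("woman", "man")) {
    brute <- Reduce(`+`, lapply(which(gender == gg), function(i)
      brute_score_emotions(g$corpus$tweets$tokens[[i]], g$emotion_lexicon)))
    sub <- tab[tab$gender == gg, ]
    expect_equal(stats::setNames(sub$count, sub$category),
                 stats::setNames(as.numeric(brute), names(brute)))
    expect_lt(abs(sum(sub$pct) - 100), 0.5)
  }
})

test_that("variance-ratio test matches hand values and quadrature", {
  s <- variance_ratio_test(c(0, 2, 4), c(0, 1, 2))
  expect_equal(s$statistic, 4)
  expect_equal(s$df, c(2L, 2L))
  expect_equal(variance_ratio_test(c(1, 2, 9), c(1, 2, 9))$statistic, 1)
  expect_error(variance_ratio_test(c(1, 2), c(3, 3)), "degenerate")

  set.seed(14)
  for (i in 1:10) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1))
    s <- variance_ratio_test(x, y)
    lower <- stats::integrate(function(t) stats::df(t, s$df[1], s$df[2]),
                              0, s$statistic, rel.tol = 1e-10)$value
    expect_equal(s$p_value, min(1, 2 * min(lower, 1 - lower)),
                 tolerance = 1e-6)
    # independent oracle: base R var.test
    vt <- stats::var.test(x, y)
    expect_equal(s$statistic, unname(vt$statistic), tolerance = 1e-12)
    expect_equal(s$p_value, vt$p.value, tolerance = 1e-12)
  }
})

test_that("rank-sum W counts dominating pairs with ties halved", {
  expect_equal(rank_sum_test(c(1, 2), c(3, 4))$statistic, 0)
  expect_equal(rank_sum_test(c(3, 4), c(1, 2))$statistic, 4)
  x <- c(2, 5, 5, 7)
  expect_equal(rank_sum_test(x, x)$statistic, length(x)^2 / 2)
  set.seed(6)
  for (i in 1:10) {   # antisymmetry without ties
    x <- rnorm(6); y <- rnorm(5)
    expect_equal(rank_sum_test(x, y)$statistic + rank_sum_test(y, x)$statistic,
                 30)
  }
})

test_that("rank-sum p follows the tie-corrected normal approximation", {
  set.seed(33)
  for (i in 1:15) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    x <- sample(1:6, n, replace = TRUE)   # ties likely
    y <- sample(1:6, m, replace = TRUE)
    mine <- rank_sum_test(x, y)
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    expect_equal(mine$statistic, unname(wt$statistic))
    expect_equal(mine$p_value, wt$p.value, tolerance = 1e-10)
    # exact enumeration bounds the approximation
    xe <- rnorm(n); ye <- rnorm(m)
    mine2 <- rank_sum_test(xe, ye)
    expect_equal(mine2$statistic,
                 sum(outer(xe, ye, ">")) + 0.5 * sum(outer(xe, ye, "==")))
    expect_lt(abs(mine2$p_value - exact_rank_sum_p(xe, ye)), 0.1)
  }
})

test_that("compare_groups is null on identical gender samples", {
  toks <- rep(list(c("good", "bad"), c("good", "good", "bad"), c("bad", "calm"),
                   c("good", "calm"), c("bad", "bad")), 2)
  corp <- make_corpus(toks, rep(c("woman", "man"), each = 5))
  cg <- compare_groups(corp, toy_emotion_lexicon(), c("joy", "positive"))
  expect_equal(cg$median_women, cg$median_men)
  expect_equal(cg$W, rep(5 * 5 / 2, 2))
  expect_true(all(cg$p_w > 0.9))
})

test_that("compare_groups agrees with a hand-computed 10-tweet sheet", {
  lex <- toy_emotion_lexicon()
  toks <- list(c("good", "bad"), c("good", "good"), c("bad", "bad"),
               c("good", "calm", "bad"), c("odd", "zzz"),
               c("good"), c("bad"), c("calm", "calm"),
               c("good", "bad", "bad"), c("calm", "bad"))
  gender <- c(rep("woman", 5), rep("man", 5))
  corp <- make_corpus(toks, gender)
  cg <- compare_groups(corp, lex, "positive")
  # per-tweet positive proportions: w: 1/2, 1, 0, 2/3, NA; m: 1, 0, 1, 1/3, 1/2
  xw <- c(1/2, 1, 0, 2/3); xm <- c(1, 0, 1, 1/3, 1/2)
  expect_equal(cg$n_women, 4L); expect_equal(cg$n_men, 5L)
  expect_equal(cg$median_women, median(xw))
  expect_equal(cg$mean_men, mean(xm))
  expect_equal(cg$F, var(xw) / var(xm))
  expect_equal(cg$W, rank_sum_test(xw, xm)$statistic)
  # tweet 5 has no sentiment words: excluded, not imputed
  expect_equal(cg$n_women + cg$n_men, 9L)
})

test_that("an emotion with no defined proportions in a gender is untestable", {
  toks <- list(c("odd"), c("odd"), c("good", "bad"), c("good"))
  corp <- make_corpus(toks, c("woman", "woman", "man", "man"))
  cg <- compare_groups(corp, toy_emotion_lexicon(), "joy")
  expect_true(cg$untestable)
  expect_true(is.na(cg$W))
})

test_that("monthly series equals a brute-force group-by", {
  g <- generate_corpus(synthetic_config(n_users = 8, tweets_per_user = 10,
                                        date_start = "2018-01-01",
                                        date_end = "2018-03-31", seed = 17))
  ms <- monthly_series(g$corpus, g$emotion_lexicon, c("joy", "negative"))
  gender <- g$corpus$users$gender[match(g$corpus$tweets$user_id,
                                        g$corpus$users$user_id)]
  month <- format(g$corpus$tweets$timestamp, "%Y-%m", tz = "UTC")
  for (e in c("joy", "negative")) {
    props <- vapply(g$corpus$tweets$tokens, function(tk)
      emotion_proportion(brute_score_emotions(tk, g$emotion_lexicon), e),
      numeric(1))
    for (r in which(ms$emotion == e)) {
      sel <- month == ms$month[r] & gender == ms$gender[r] & !is.na(props)
      expect_equal(ms$mean[r], mean(props[sel]))
      expect_equal(ms$n[r], sum(sel))
      expect_gte(ms$mean[r], min(props[sel]))
      expect_lte(ms$mean[r], max(props[sel]))
    }
  }
})

test_that("gender-label permutation rejects at about the nominal rate", {
  g <- generate_corpus(synthetic_config(n_users = 30, tweets_per_user = 6,
                                        emission = null_emission(), seed = 55))
  props <- vapply(g$corpus$tweets$tokens, function(tk)
    emotion_proportion(brute_score_emotions(tk, g$emotion_lexicon), "joy"),
    numeric(1))
  gender <- g$corpus$users$gender[match(g$corpus$tweets$user_id,
                                        g$corpus$users$user_id)]
  ok <- !is.na(props)
  props <- props[ok]; gender <- gender[ok]
  set.seed(99)
  rejections <- replicate(500, {
    perm <- sample(gender)
    rank_sum_test(props[perm == "woman"], props[perm == "man"])$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.01)
  expect_lte(mean(rejections), 0.10)
})
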