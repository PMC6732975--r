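fake_model <- function(phi, theta, vocab = colnames(phi)) {
  structure(list(K = nrow(phi), topic_word = phi, doc_topic = theta,
                 alpha = 1, beta = 0.1, seed = 1L,
                 vocab = vocab, doc_ids = paste0("d", seq_len(nrow(theta))),
                 doc_lengths = rep(10, nrow(theta))),
            class = "lda_model")
}

test_that("label_topics matches independent arithmetic on a 3x6 toy model", {
  vocab <- c("apple", "berry", "cedar", "daisy", "elm", "fig")
  set.seed(3)
  phi <- matrix(stats::rexp(18), 3, 6, dimnames = list(NULL, vocab))
  phi <- phi / rowSums(phi)
  theta <- matrix(1 / 3, 4, 3)
  m <- fake_model(phi, theta)
  prof <- label_topics(m, n = 6, frex_weight = 0.5)
  ex <- sweep(phi, 2, colSums(phi), "/")
  for (k in 1:3) {
    expect_equal(prof$highest_probability[prof$topic == k],
                 vocab[order(-phi[k, ], vocab)])
    Fex <- sapply(seq_along(vocab), function(v) mean(ex[k, ] <= ex[k, v]))
    Ffr <- sapply(seq_along(vocab), function(v) mean(phi[k, ] <= phi[k, v]))
    frex <- 1 / (0.5 / Fex + 0.5 / Ffr)
    expect_equal(prof$frex[prof$topic == k], vocab[order(-frex, vocab)])
    sc <- phi[k, ] * (log(phi[k, ]) - colMeans(log(phi)))
    expect_equal(prof$score[prof$topic == k], vocab[order(-sc, vocab)])
  }
})

test_that("frex_weight 0 reduces FREX to the frequency ordering", {
  vocab <- letters[1:5]
  set.seed(13)
  phi <- matrix(stats::rexp(10), 2, 5, dimnames = list(NULL, vocab))
  phi <- phi / rowSums(phi)
  prof <- label_topics(fake_model(phi, matrix(0.5, 3, 2)), n = 5,
                       frex_weight = 0)
  expect_equal(prof$frex, prof$highest_probability)
})

test_that("K = 1 makes probability and FREX orders coincide with frequency", {
  vocab <- letters[1:6]
  phi <- matrix(c(0.3, 0.25, 0.2, 0.15, 0.07, 0.03), 1,
                dimnames = list(NULL, vocab))
  prof <- label_topics(fake_model(phi, matrix(1, 3, 1)), n = 6)
  expect_equal(prof$highest_probability, vocab)
  expect_equal(prof$frex, vocab)
})

test_that("semantic coherence follows the co-occurrence formula", {
  vocab <- c("a", "b")
  phi <- matrix(c(0.7, 0.3), 1, dimnames = list(NULL, vocab))
  # never co-occurring, one doc each
  d <- build_dtm(list("a", "b"))
  m <- fake_model(phi, matrix(1, 2, 1))
  expect_equal(semantic_coherence(m, d, top_m = 2), log(1 / 1))
  # co-occurring in every one of two documents: log((2+1)/2)
  d2 <- build_dtm(list(c("a", "b"), c("a", "b")))
  expect_equal(semantic_coherence(m, d2, top_m = 2), log(3 / 2))
  expect_error(semantic_coherence(m, d2, top_m = 1), "top_m")
})

test_that("semantic coherence matches the double-loop oracle on random data", {
  set.seed(47)
  for (i in 1:5) {
    toks <- lapply(1:12, function(j)
      sample(letters[1:10], sample(3:9, 1), replace = TRUE))
    d <- build_dtm(toks)
    K <- 3
    phi <- matrix(stats::rexp(K * ncol(d)), K, ncol(d),
                  dimnames = list(NULL, colnames(d)))
    phi <- phi / rowSums(phi)
    m <- fake_model(phi, matrix(1 / K, nrow(d), K))
    co <- semantic_coherence(m, d, top_m = 5)
    for (k in 1:K) {
      words <- colnames(d)[order(-phi[k, ], colnames(d))[1:5]]
      expect_equal(co[k], brute_coherence(words, as.matrix(d)))
    }
  }
})

test_that("prevalence effects are null, antisymmetric and compositional", {
  set.seed(7)
  theta <- matrix(stats::rexp(60 * 4), 60, 4)
  theta <- theta / rowSums(theta)
  phi <- matrix(1 / 6, 4, 6, dimnames = list(NULL, letters[1:6]))
  m <- fake_model(phi, theta)
  # same distribution in both groups (labels alternate over identical rows)
  theta_dup <- theta[rep(1:30, 2), ]
  m2 <- fake_model(phi, theta_dup)
  g2 <- rep(c("woman", "man"), each = 30)
  pv <- estimate_prevalence(m2, g2, n_boot = 200, seed = 1)
  expect_true(all(abs(pv$effect) < 1e-12))
  expect_true(all(pv$label == "indeterminate"))
  # swapping labels negates effects exactly
  g <- sample(c("woman", "man"), 60, replace = TRUE)
  p1 <- estimate_prevalence(m, g, n_boot = 50, seed = 2)
  gs <- ifelse(g == "woman", "man", "woman")
  p2 <- estimate_prevalence(m, gs, n_boot = 50, seed = 2)
  expect_equal(p1$effect, -p2$effect)
  expect_lt(abs(sum(p1$effect)), 1e-9)
  expect_error(estimate_prevalence(m, rep("woman", 60), n_boot = 10, seed = 1),
               "0 documents")
  expect_error(estimate_prevalence(m, rep(c("woman", "unknown"), 30),
                                   n_boot = 10, seed = 1), "non-unknown")
})

test_that("topic correlations: two-part compositions are anticorrelated", {
  set.seed(27)
  theta <- matrix(stats::rexp(40), 20, 2)
  theta <- theta / rowSums(theta)
  phi <- matrix(1 / 4, 2, 4, dimnames = list(NULL, letters[1:4]))
  r <- topic_correlations(fake_model(phi, theta))
  expect_equal(diag(r), c(1, 1))
  expect_equal(r[1, 2], -1)
  expect_equal(r, t(r))
  # degenerate: identical rows give zero variance -> 0 with warning
  theta0 <- matrix(rep(c(0.2, 0.3, 0.5), each = 5), 5, 3)
  expect_warning(r0 <- topic_correlations(fake_model(matrix(1 / 4, 3, 4,
    dimnames = list(NULL, letters[1:4])), theta0)), "zero-variance")
  expect_equal(r0[1, 2], 0)
  expect_equal(diag(r0), rep(1, 3))
})

test_that("topic happiness: hand OLS, degenerate flatness, null pairs", {
  prof <- tibble::tibble(topic = 1:3, rank = 1,
                         highest_probability = c("lowword", "midword", "highword"),
                         frex = highest_probability,
                         score = highest_probability)
  prev <- tibble::tibble(topic = 1:3, effect = c(-0.1, 0, 0.1),
                         ci_lower = 0, ci_upper = 0,
                         label = c("more likely men", "indeterminate",
                                   "more likely women"))
  lex <- happiness_lexicon(c(lowword = 2, midword = 5, highword = 8))
  th <- topic_happiness_analysis(prof, prev, lex)
  expect_equal(th$regression$slope, 3.0)
  expect_equal(th$per_topic$rank, 1:3)
  # all scores equal -> flat, flagged by p = 1
  lex_flat <- happiness_lexicon(c(lowword = 5, midword = 5, highword = 5))
  th_flat <- topic_happiness_analysis(prof, prev, lex_flat)
  expect_equal(th_flat$regression$slope, 0)
  expect_equal(th_flat$regression$p_value, 1)
  # identical word lists compare as a perfect null
  prof2 <- tibble::tibble(topic = rep(1:2, each = 2), rank = rep(1:2, 2),
                          highest_probability = rep(c("lowword", "highword"), 2),
                          frex = highest_probability,
                          score = highest_probability)
  prev2 <- prev[1:2, ]
  th2 <- topic_happiness_analysis(prof2, prev2, lex)
  expect_equal(th2$pairwise$W, 2^2 / 2)
  expect_gt(th2$pairwise$p_value, 0.9)
  # unmatched topic excluded from the regression with a warning
  lex_partial <- happiness_lexicon(c(lowword = 2, midword = 5))
  expect_warning(th3 <- topic_happiness_analysis(prof, prev, lex_partial),
                 "excluded")
  expect_equal(th3$per_topic$n[3], 0L)
})
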