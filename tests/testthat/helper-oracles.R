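# Shared fixtures and independent brute-force oracles used across the suite.

toy_emotion_lexicon <- function() {
  emotion_lexicon(list(
    good = c("joy", "positive"),
    bad = c("sadness", "negative"),
    calm = c("trust", "positive"),
    dread = c("fear", "negative"),
    odd = "surprise"
  ))
}

# build a minimal gendered corpus from token lists
make_corpus <- function(tokens, genders, dates = NULL) {
  n <- length(tokens)
  if (is.null(dates)) dates <- rep("2018-06-01", n)
  users <- tibble::tibble(
    user_id = paste0("u", seq_len(n)),
    gender = genders,
    lifetime_tweet_count = 10L)
  tweets <- tibble::tibble(
    tweet_id = paste0("t", seq_len(n)),
    user_id = paste0("u", seq_len(n)),
    timestamp = as.POSIXct(dates, tz = "UTC"),
    text = vapply(tokens, paste, character(1), collapse = " "),
    tokens = tokens)
  tweet_corpus(tweets, users)
}

# literal per-token, per-category double loop
brute_score_emotions <- function(tokens, lexicon) {
  cats <- emotion_categories()
  out <- stats::setNames(integer(length(cats)), cats)
  for (tk in tokens) {
    assoc <- unclass(lexicon)[[tk]]
    for (a in assoc) out[a] <- out[a] + 1L
  }
  out
}

# dense tally over a token list
brute_dtm <- function(tokens) {
  vocab <- sort(unique(unlist(tokens)))
  m <- matrix(0L, length(tokens), length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(tokens))
    for (tk in tokens[[i]]) m[i, tk] <- m[i, tk] + 1L
  m
}

# literal mean-over-containing-documents TF-IDF
brute_tfidf <- function(m) {
  D <- nrow(m)
  len <- rowSums(m)
  sapply(colnames(m), function(v) {
    docs <- which(m[, v] > 0)
    if (!length(docs)) return(NA_real_)
    mean(m[docs, v] / len[docs]) * log2(D / length(docs))
  })
}

# literal double loop over the chosen top words
brute_coherence <- function(words, m) {
  bin <- m > 0
  total <- 0
  for (i in 2:length(words)) {
    for (j in seq_len(i - 1)) {
      dj <- sum(bin[, words[j]])
      if (dj == 0) next
      dij <- sum(bin[, words[i]] & bin[, words[j]])
      total <- total + log((dij + 1) / dj)
    }
  }
  total
}

# exact two-sided rank-sum p by enumerating all C(n+m, n) group labelings
exact_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(x, y)
  combos <- utils::combn(length(pooled), n)
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mu <- n * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# best topic-row alignment by exhaustive permutation (K small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

perm_matched_cosine <- function(phi_est, phi_true) {
  stopifnot(nrow(phi_est) == nrow(phi_true))
  en <- phi_est / sqrt(rowSums(phi_est^2))
  tn <- phi_true / sqrt(rowSums(phi_true^2))
  cs <- en %*% t(tn)
  max(apply(all_perms(nrow(cs)), 1, function(p)
    mean(cs[cbind(seq_len(nrow(cs)), p)])))
}

# emission config with the women-joy excess planted and all else equal
joy_excess_emission <- function() {
  em <- default_emission_rates()
  em["woman", ] <- em["man", ]
  em["woman", "joy"] <- 0.06
  em["man", "joy"] <- 0.04
  em
}

null_emission <- function() {
  em <- default_emission_rates()
  em["woman", ] <- em["man", ]
  em
}

# planted-topic fixture: V = 200, K = 5, D = 1000, 30 tokens/doc
topic_fixture_config <- function(seed) {
  synthetic_config(n_users = 50, tweets_per_user = 10,
                   emission = default_emission_rates() * 0, n_fillers = 0,
                   topic_words_per_topic = 40, K_true = 5,
                   tokens_per_tweet = 30, tokens_fixed = TRUE,
                   neutral_topic_mass = 0, seed = seed)
}
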