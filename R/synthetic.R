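#' Default per-gender emotion-word emission rates
#'
#' Probability, per token, of emitting a word from each emotion-lexicon
#' category, by author gender. The defaults plant the effect directions the
#' analysis is designed to detect: women elevated on joy, trust,
#' anticipation and positive; men elevated on fear, sadness, disgust and
#' negative; anger slightly higher in men and surprise equal. Per-gender
#' totals stay well below 1; the remaining mass is emitted from the
#' document's topics.
#'
#' @return 2 x 10 matrix (rows "woman", "man"; columns
#'   [emotion_categories()]).
#' @export
default_emission_rates <- function() {
  cats <- emotion_categories()
  woman <- c(anger = 0.020, anticipation = 0.050, disgust = 0.015,
             fear = 0.030, joy = 0.060, sadness = 0.025, surprise = 0.020,
             trust = 0.060, negative = 0.050, positive = 0.080)
  man <- c(anger = 0.025, anticipation = 0.040, disgust = 0.020,
           fear = 0.040, joy = 0.040, sadness = 0.035, surprise = 0.020,
           trust = 0.050, negative = 0.065, positive = 0.070)
  rbind(woman = woman[cats], man = man[cats])
}

#' Synthetic corpus configuration
#'
#' All knobs of the synthetic-corpus generator, with defaults emulating the
#' structure the pipeline assumes: two author groups with gender-shifted
#' emotion-word emission rates, K planted topics with a gender-shifted
#' prevalence on topic 1, emotion-linked word happiness scores, and
#' multi-year uniform timestamps.
#'
#' @param n_users Users per gender.
#' @param tweets_per_user Collected tweets per user.
#' @param date_start,date_end Study window (UTC dates).
#' @param emotion_words_per_category Generated words per emotion category.
#' @param n_fillers Neutral filler words shared across topics.
#' @param topic_words_per_topic Topic-specific words per planted topic.
#' @param K_true Number of planted topics.
#' @param topic_concentration Dirichlet concentration for per-document topic
#'   proportions (higher = less variable documents).
#' @param emission 2 x 10 per-gender emission probability matrix
#'   ([default_emission_rates()]). Rows must sum to <= 1.
#' @param prevalence_shift Half-gap planted on topic 1: women's mean
#'   prevalence of topic 1 is `1/K + prevalence_shift`, men's is
#'   `1/K - prevalence_shift`, so the woman-man effect is
#'   `2 * prevalence_shift` (default 0.05, i.e. a +0.10 effect).
#' @param neutral_topic_mass Share of every planted topic's mass spread
#'   uniformly over the fillers (0 when `n_fillers = 0`).
#' @param happiness_means Named means of the generated word happiness scores
#'   for the positive-pole categories, negative-pole categories and
#'   neutral/topic words.
#' @param happiness_sd Spread of generated happiness scores.
#' @param tokens_per_tweet Mean tokens per tweet (Poisson, minimum 1), or
#'   the exact count when `tokens_fixed = TRUE`.
#' @param tokens_fixed Use a constant token count per tweet.
#' @param seed Integer RNG seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_users = 200L, tweets_per_user = 50L,
                             date_start = "2007-08-01", date_end = "2018-12-01",
                             emotion_words_per_category = 30L, n_fillers = 200L,
                             topic_words_per_topic = 40L, K_true = 5L,
                             topic_concentration = 10,
                             emission = default_emission_rates(),
                             prevalence_shift = 0.05,
                             neutral_topic_mass = if (n_fillers > 0) 0.2 else 0,
                             happiness_means = c(positive_pole = 7,
                                                 negative_pole = 3, neutral = 5),
                             happiness_sd = 0.5,
                             tokens_per_tweet = 12, tokens_fixed = FALSE,
                             seed = 1L) {
  cfg <- list(n_users = as.integer(n_users),
              tweets_per_user = as.integer(tweets_per_user),
              date_start = date_start, date_end = date_end,
              emotion_words_per_category = as.integer(emotion_words_per_category),
              n_fillers = as.integer(n_fillers),
              topic_words_per_topic = as.integer(topic_words_per_topic),
              K_true = as.integer(K_true),
              topic_concentration = topic_concentration,
              emission = emission, prevalence_shift = prevalence_shift,
              neutral_topic_mass = neutral_topic_mass,
              happiness_means = happiness_means, happiness_sd = happiness_sd,
              tokens_per_tweet = tokens_per_tweet,
              tokens_fixed = isTRUE(tokens_fixed), seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (!identical(rownames(cfg$emission), c("woman", "man")) ||
      !identical(colnames(cfg$emission), emotion_categories()))
    stop("emission must be a 2 x 10 matrix with rows woman/man and the fixed categories")
  if (any(rowSums(cfg$emission) > 1))
    stop("per-gender emission probabilities must sum to <= 1")
  if (any(cfg$emission < 0)) stop("emission probabilities must be nonnegative")
  if (cfg$K_true < 1) stop("K_true must be >= 1")
  if (cfg$topic_words_per_topic < 1 && cfg$n_fillers < 1)
    stop("inconsistent vocabulary sizes: topics need topic words or fillers")
  if (cfg$n_fillers == 0 && cfg$neutral_topic_mass > 0)
    stop("inconsistent vocabulary sizes: neutral_topic_mass > 0 needs fillers")
  if (cfg$prevalence_shift < 0 || cfg$prevalence_shift >= 1 / cfg$K_true)
    stop("prevalence_shift must lie in [0, 1/K_true)")
  if (as.Date(cfg$date_end) < as.Date(cfg$date_start))
    stop("date_end precedes date_start")
  invisible(cfg)
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic corpus with recorded ground truth
#'
#' Draws a gendered user panel and, for each tweet, gender-conditional topic
#' proportions (Dirichlet with a gender-shifted mean) and tokens that come
#' either from an emotion category (with the per-gender emission
#' probability, uniform within the category's word list) or from the active
#' topic's word distribution. Also builds the matching emotion and
#' happiness lexicons and records every planted parameter and per-token
#' provenance. Fully deterministic given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `corpus` (a `tweet_corpus`, already tokenized),
#'   `emotion_lexicon`, `happiness_lexicon` and `ground_truth` (planted
#'   topic-word rows, per-document gender/theta, per-token provenance,
#'   emission rates, prevalence means and the config).
#' @export
generate_corpus <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  cats <- emotion_categories()
  K <- config$K_true

  # --- vocabularies -------------------------------------------------------
  emo_words <- lapply(cats, function(cc)
    sprintf("%sword%03d", cc, seq_len(config$emotion_words_per_category)))
  names(emo_words) <- cats
  fillers <- if (config$n_fillers > 0)
    sprintf("fillerword%03d", seq_len(config$n_fillers)) else character(0)
  topic_blocks <- lapply(seq_len(K), function(k)
    if (config$topic_words_per_topic > 0)
      sprintf("t%dword%03d", k, seq_len(config$topic_words_per_topic))
    else character(0))
  topic_vocab <- c(unlist(topic_blocks), fillers)

  # planted topic-word rows: own block plus a shared neutral filler slab
  phi_true <- matrix(0, K, length(topic_vocab),
                     dimnames = list(NULL, topic_vocab))
  for (k in seq_len(K)) {
    own <- topic_blocks[[k]]
    if (length(own)) {
      w <- as.numeric(rdirichlet(1, rep(5, length(own))))
      phi_true[k, own] <- (1 - config$neutral_topic_mass) * w
    }
    if (length(fillers))
      phi_true[k, fillers] <- phi_true[k, fillers] +
        (config$neutral_topic_mass + (length(own) == 0) *
           (1 - config$neutral_topic_mass)) / length(fillers)
  }

  # --- lexicons -----------------------------------------------------------
  pos_pole <- c("joy", "trust", "anticipation")
  neg_pole <- c("anger", "disgust", "fear", "sadness")
  assoc <- list()
  for (cc in cats) {
    extra <- if (cc %in% pos_pole) "positive" else
      if (cc %in% neg_pole) "negative" else NULL
    for (w in emo_words[[cc]]) assoc[[w]] <- c(cc, extra)
  }
  emo_lex <- emotion_lexicon(assoc)

  hm <- config$happiness_means
  word_mean <- function(cc) {
    if (cc %in% c(pos_pole, "positive")) hm[["positive_pole"]]
    else if (cc %in% c(neg_pole, "negative")) hm[["negative_pole"]]
    else hm[["neutral"]]
  }
  all_words <- c(unlist(emo_words), topic_vocab)
  mu <- c(unlist(lapply(cats, function(cc)
    rep(word_mean(cc), length(emo_words[[cc]])))),
    rep(hm[["neutral"]], length(topic_vocab)))
  hap_scores <- pmin(9, pmax(1, rnorm(length(all_words), mu, config$happiness_sd)))
  hap_lex <- happiness_lexicon(setNames(hap_scores, all_words))

  # --- users --------------------------------------------------------------
  n_u <- config$n_users
  users <- tibble(
    user_id = c(sprintf("w%04d", seq_len(n_u)), sprintf("m%04d", seq_len(n_u))),
    gender = rep(c("woman", "man"), each = n_u))
  D_per_user <- config$tweets_per_user
  users$lifetime_tweet_count <- as.integer(D_per_user *
    sample(3:9, 2 * n_u, replace = TRUE))
  users$follower_count <- as.integer(rpois(2 * n_u, 400))
  users$country <- sample(c("US", "GB", "CA", "AU", NA), 2 * n_u,
                          replace = TRUE, prob = c(0.45, 0.25, 0.08, 0.07, 0.15))
  list_pool <- sprintf("list%02d", 1:10)
  users$list_memberships <- lapply(sample(3:6, 2 * n_u, replace = TRUE),
                                   function(k) sample(list_pool, k))

  # --- documents ----------------------------------------------------------
  D <- 2L * n_u * D_per_user
  doc_user <- rep(users$user_id, each = D_per_user)
  doc_gender <- rep(users$gender, each = D_per_user)
  base <- rep(1 / K, K)
  shift1 <- c(config$prevalence_shift,
              rep(-config$prevalence_shift / max(1, K - 1), K - 1))
  prev_mean <- rbind(woman = base + shift1, man = base - shift1)
  theta <- matrix(NA_real_, D, K)
  for (g in c("woman", "man")) {
    sel <- doc_gender == g
    theta[sel, ] <- rdirichlet(sum(sel),
                               config$topic_concentration * prev_mean[g, ])
  }

  n_tok <- if (config$tokens_fixed) rep(as.integer(config$tokens_per_tweet), D)
    else pmax(1L, rpois(D, config$tokens_per_tweet))
  start <- as.POSIXct(paste0(config$date_start, " 00:00:00"), tz = "UTC")
  end <- as.POSIXct(paste0(config$date_end, " 23:59:59"), tz = "UTC")
  stamps <- start + round(runif(D, 0, as.numeric(difftime(end, start, units = "secs"))))

  # --- tokens -------------------------------------------------------------
  N <- sum(n_tok)
  tok_doc <- rep.int(seq_len(D), n_tok)
  tok_gender_w <- doc_gender[tok_doc] == "woman"
  u <- runif(N)
  cum_w <- cumsum(config$emission["woman", ])
  cum_m <- cumsum(config$emission["man", ])
  cat_idx <- integer(N)
  cat_idx[tok_gender_w] <- findInterval(u[tok_gender_w], c(0, cum_w))
  cat_idx[!tok_gender_w] <- findInterval(u[!tok_gender_w], c(0, cum_m))
  is_emo <- cat_idx <= length(cats)           # beyond the last cut: topic token

  word <- character(N)
  provenance <- character(N)
  for (ci in seq_along(cats)) {
    sel <- which(is_emo & cat_idx == ci)
    if (!length(sel)) next
    word[sel] <- emo_words[[ci]][ceiling(runif(length(sel)) *
                                           length(emo_words[[ci]]))]
    provenance[sel] <- cats[ci]
  }
  topic_tok <- which(!is_emo)
  if (length(topic_tok)) {
    theta_cum <- theta %*% upper.tri(diag(K), diag = TRUE)
    u2 <- runif(length(topic_tok))
    z <- K + 1L - rowSums(u2 <= theta_cum[tok_doc[topic_tok], , drop = FALSE])
    for (k in seq_len(K)) {
      sel <- topic_tok[z == k]
      if (!length(sel)) next
      word[sel] <- sample(topic_vocab, length(sel), replace = TRUE,
                          prob = phi_true[k, ])
    }
    provenance[topic_tok] <- paste0("topic", z)
  }

  tokens <- split(word, factor(tok_doc, levels = seq_len(D)))
  names(tokens) <- NULL
  tweets <- tibble(
    tweet_id = sprintf("t%07d", seq_len(D)),
    user_id = doc_user,
    timestamp = stamps,
    text = vapply(tokens, paste, character(1), collapse = " "),
    tokens = tokens)
  corpus <- tweet_corpus(tweets, users)

  ground_truth <- list(
    topic_word = phi_true,
    doc_gender = doc_gender,
    doc_topic = theta,
    token_provenance = unname(split(provenance, factor(tok_doc, levels = seq_len(D)))),
    emission = config$emission,
    prevalence_means = prev_mean,
    happiness_scores = setNames(hap_scores, all_words),
    config = config)
  list(corpus = corpus, emotion_lexicon = emo_lex,
       happiness_lexicon = hap_lex, ground_truth = ground_truth)
}
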