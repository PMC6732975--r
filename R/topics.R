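#' Gender effect on topical prevalence
#'
#' For each topic, the prevalence effect is the difference in mean
#' document-topic proportion between women- and men-authored documents
#' (`E[theta_k | woman] - E[theta_k | man]`), with a percentile confidence
#' interval from a stratified nonparametric bootstrap over documents. A topic
#' is labelled "more likely women"/"more likely men" only when the interval
#' excludes 0. Effects sum to zero over topics (compositionality).
#'
#' @param model An `lda_model`.
#' @param gender Character vector, one `"woman"`/`"man"` per document.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer RNG seed.
#' @param conf Confidence level (default 0.95).
#' @return Tibble: topic, effect, ci_lower, ci_upper, label.
#' @export
estimate_prevalence <- function(model, gender, n_boot = 1000L, seed = 1L,
                                conf = 0.95) {
  theta <- model$doc_topic
  if (length(gender) != nrow(theta))
    stop("gender must have one value per document")
  bad <- setdiff(unique(gender), c("woman", "man"))
  if (length(bad))
    stop("every document needs a non-unknown gender; found: ",
         paste(bad, collapse = ", "))
  iw <- which(gender == "woman"); im <- which(gender == "man")
  if (!length(iw) || !length(im)) stop("a gender has 0 documents")
  effect <- colMeans(theta[iw, , drop = FALSE]) -
    colMeans(theta[im, , drop = FALSE])
  set.seed(as.integer(seed))
  boots <- matrix(NA_real_, n_boot, model$K)
  for (b in seq_len(n_boot)) {
    bw <- iw[sample.int(length(iw), replace = TRUE)]
    bm <- im[sample.int(length(im), replace = TRUE)]
    boots[b, ] <- colMeans(theta[bw, , drop = FALSE]) -
      colMeans(theta[bm, , drop = FALSE])
  }
  a <- (1 - conf) / 2
  lo <- apply(boots, 2, quantile, probs = a)
  hi <- apply(boots, 2, quantile, probs = 1 - a)
  label <- ifelse(lo > 0, "more likely women",
                  ifelse(hi < 0, "more likely men", "indeterminate"))
  tibble(topic = seq_len(model$K), effect = effect,
         ci_lower = lo, ci_upper = hi, label = label)
}

# per-word exclusivity: share of the word's topic mass owned by each topic
topic_exclusivity_matrix <- function(topic_word) {
  sweep(topic_word, 2, colSums(topic_word), "/")
}

#' Topic word profiles: highest probability, FREX and score
#'
#' Three orderings of each topic's vocabulary: raw topic-word probability;
#' FREX, the weighted harmonic mean of the within-topic empirical-CDF ranks
#' of exclusivity and of probability (`frex_weight` on exclusivity); and the
#' term score `phi * (log phi - mean_k log phi)`. Ties are broken
#' lexicographically on the word form.
#'
#' @param model An `lda_model`.
#' @param n Words per list (default 20; must not exceed the vocabulary).
#' @param frex_weight Weight on exclusivity in \[0, 1\] (default 0.5).
#' @return Tibble: topic, rank, highest_probability, frex, score (words).
#' @export
label_topics <- function(model, n = 20L, frex_weight = 0.5) {
  phi <- model$topic_word
  vocab <- model$vocab
  if (n > length(vocab)) stop("n exceeds the vocabulary size")
  ex <- topic_exclusivity_matrix(phi)
  eps <- 1e-300
  logphi <- log(pmax(phi, eps))
  score <- phi * (logphi - matrix(colMeans(logphi), nrow(phi), ncol(phi),
                                  byrow = TRUE))
  top_n <- function(v) vocab[order(-v, vocab)[seq_len(n)]]
  rows <- lapply(seq_len(model$K), function(k) {
    ecdf_ex <- stats::ecdf(ex[k, ])(ex[k, ])
    ecdf_fr <- stats::ecdf(phi[k, ])(phi[k, ])
    frex <- 1 / (frex_weight / ecdf_ex + (1 - frex_weight) / ecdf_fr)
    tibble(topic = k, rank = seq_len(n),
           highest_probability = top_n(phi[k, ]),
           frex = top_n(frex),
           score = top_n(score[k, ]))
  })
  dplyr::bind_rows(rows)
}

#' Semantic coherence of each topic
#'
#' Mimno-style co-occurrence score over each topic's `top_m`
#' probability-ranked words: `sum_{i=2..M} sum_{j<i}
#' log((D(v_i, v_j) + 1) / D(v_j))`, where `D` counts documents containing
#' the word(s). Always <= 0; closer to 0 means the top words co-occur more.
#'
#' @param model An `lda_model`.
#' @param dtm The document-term matrix the model was fitted on.
#' @param top_m Number of top words (>= 2, default 10).
#' @return Numeric vector, one value per topic.
#' @export
semantic_coherence <- function(model, dtm, top_m = 10L) {
  if (top_m < 2) stop("top_m must be >= 2")
  top_m <- min(top_m, length(model$vocab))
  vocab <- model$vocab
  bin <- methods::as(dtm > 0, "CsparseMatrix") * 1
  vapply(seq_len(model$K), function(k) {
    words <- vocab[order(-model$topic_word[k, ], vocab)[seq_len(top_m)]]
    sub <- bin[, words, drop = FALSE]
    co <- as.matrix(Matrix::crossprod(sub))       # document co-occurrence
    dfreq <- diag(co)
    total <- 0
    for (i in 2:top_m) {
      for (j in seq_len(i - 1)) {
        if (dfreq[j] == 0) {
          warning("top word '", words[j], "' occurs in no document; pair skipped")
          next
        }
        total <- total + log((co[i, j] + 1) / dfreq[j])
      }
    }
    total
  }, numeric(1))
}

#' Per-topic quality diagnostics
#'
#' Semantic coherence plus an exclusivity summary (mean, over the topic's
#' `top_m` highest-probability words, of the share of each word's total
#' topic mass owned by the topic; in \[0, 1\]).
#'
#' @inheritParams semantic_coherence
#' @return Tibble: topic, semantic_coherence, exclusivity.
#' @export
topic_diagnostics <- function(model, dtm, top_m = 10L) {
  ex <- topic_exclusivity_matrix(model$topic_word)
  excl <- vapply(seq_len(model$K), function(k) {
    idx <- order(-model$topic_word[k, ], model$vocab)[seq_len(min(top_m, ncol(ex)))]
    mean(ex[k, idx])
  }, numeric(1))
  tibble(topic = seq_len(model$K),
         semantic_coherence = semantic_coherence(model, dtm, top_m),
         exclusivity = excl)
}

#' Between-topic correlations
#'
#' Pearson correlations, across documents, of the centered-log-ratio
#' transformed document-topic proportions — a compositional surrogate for
#' the logistic-normal covariance of a correlated topic model. Zero-variance
#' columns yield 0 with a warning; the diagonal is exactly 1.
#'
#' @param model An `lda_model` with K >= 2 fitted on >= 3 documents.
#' @return K x K symmetric correlation matrix.
#' @export
topic_correlations <- function(model) {
  theta <- model$doc_topic
  if (model$K < 2) stop("topic correlations need K >= 2")
  if (nrow(theta) < 3) stop("topic correlations need at least 3 documents")
  clr <- log(pmax(theta, 1e-300))
  clr <- clr - rowMeans(clr)
  sds <- apply(clr, 2, sd)
  r <- suppressWarnings(stats::cor(clr))
  if (any(sds == 0)) {
    warning("zero-variance topic column(s); correlations set to 0")
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  r
}

#' Topic happiness analysis
#'
#' Scores each topic's top highest-probability words with the happiness
#' lexicon, orders topics by their gender-prevalence effect (most-men first,
#' rank 1..K), regresses the word-level happiness scores on topic rank
#' (two-sided slope test), and compares every topic pair's word score lists
#' with the rank-sum test.
#'
#' @param profiles Output of [label_topics()].
#' @param prevalence Output of [estimate_prevalence()] over the same topics.
#' @param lexicon A `happiness_lexicon`.
#' @return List with `per_topic` (topic, rank, label, mean, sd, n,
#'   n_unmatched), `regression` (slope, intercept, p_value, n_words) and
#'   `pairwise` (topic_a, topic_b, W, p_value).
#' @export
topic_happiness_analysis <- function(profiles, prevalence, lexicon) {
  topics <- sort(unique(profiles$topic))
  if (!setequal(topics, prevalence$topic))
    stop("profiles and prevalence must cover the same topics")
  word_lists <- lapply(topics, function(k)
    profiles$highest_probability[profiles$topic == k])
  scores <- lapply(word_lists, function(w) {
    h <- happiness_score(lexicon, w)
    h[!is.na(h)]
  })
  rank_order <- order(prevalence$effect)          # most-men ... most-women
  topic_rank <- match(topics, prevalence$topic[rank_order])

  per_topic <- dplyr::bind_rows(lapply(seq_along(topics), function(i) {
    s <- set_happiness(word_lists[[i]], lexicon)
    tibble(topic = topics[i], rank = topic_rank[i],
           label = prevalence$label[match(topics[i], prevalence$topic)],
           mean = s$mean, sd = s$sd, n = s$n, n_unmatched = s$n_unmatched)
  }))

  usable <- lengths(scores) > 0
  if (!all(usable))
    warning(sum(!usable), " topic(s) with no lexicon-matched words excluded from the regression")
  reg_df <- data.frame(
    score = unlist(scores[usable]),
    rank = rep(topic_rank[usable], lengths(scores[usable])))
  regression <- list(slope = NA_real_, intercept = NA_real_,
                     p_value = NA_real_, n_words = nrow(reg_df))
  if (nrow(reg_df) >= 3 && length(unique(reg_df$rank)) >= 2) {
    if (var(reg_df$score) == 0) {
      regression$slope <- 0
      regression$intercept <- reg_df$score[1]
      regression$p_value <- 1
    } else {
      fit <- lm(score ~ rank, data = reg_df)
      cf <- suppressWarnings(summary(fit))$coefficients
      regression$slope <- cf["rank", "Estimate"]
      regression$intercept <- cf["(Intercept)", "Estimate"]
      regression$p_value <- cf["rank", "Pr(>|t|)"]
    }
  }

  pairs <- utils::combn(seq_along(topics), 2)
  pairwise <- dplyr::bind_rows(apply(pairs, 2, function(ij) {
    a <- scores[[ij[1]]]; b <- scores[[ij[2]]]
    if (!length(a) || !length(b))
      return(tibble(topic_a = topics[ij[1]], topic_b = topics[ij[2]],
                    W = NA_real_, p_value = NA_real_))
    rt <- rank_sum_test(a, b)
    tibble(topic_a = topics[ij[1]], topic_b = topics[ij[2]],
           W = rt$statistic, p_value = rt$p_value)
  }))
  list(per_topic = per_topic, regression = regression, pairwise = pairwise)
}
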