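#' Fit LDA by collapsed Gibbs sampling
#'
#' Latent Dirichlet allocation over a document-term matrix, sampled with a
#' collapsed Gibbs chain over token-topic assignments. `topic_word` (K x V)
#' and `doc_topic` (D x K) are posterior-mean estimates averaged over the
#' post-burn-in sweeps. Fully deterministic given `seed`.
#'
#' @param dtm Sparse document-term matrix ([build_dtm()]). Documents with no
#'   tokens receive a uniform topic distribution.
#' @param K Number of topics (1 <= K <= vocabulary size).
#' @param alpha Document-topic Dirichlet concentration (default `50 / K`).
#' @param beta Topic-word Dirichlet concentration (default 0.1).
#' @param n_iter Total Gibbs sweeps (default 500).
#' @param burn_in Sweeps discarded before averaging (default `n_iter / 2`);
#'   must be < `n_iter`.
#' @param seed Integer RNG seed.
#' @return An object of class `lda_model`: list with `K`, `topic_word`,
#'   `doc_topic`, `alpha`, `beta`, `seed`, `assignments` (final token-topic
#'   labels), `loglik` (post-burn-in `log p(w | z)` samples), `loglik_trace`
#'   (all sweeps), `vocab`, `doc_ids`, `doc_lengths`.
#' @export
fit_lda_gibbs <- function(dtm, K, alpha = 50 / K, beta = 0.1,
                          n_iter = 500L, burn_in = n_iter %/% 2L, seed = 1L) {
  if (K < 1) stop("K must be >= 1")
  if (K > ncol(dtm)) stop("K exceeds the vocabulary size")
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  dtm <- methods::as(dtm, "CsparseMatrix")
  trip <- Matrix::summary(dtm)                     # i, j, x triplets
  words <- rep.int(as.integer(trip$j), trip$x) - 1L
  docs <- rep.int(as.integer(trip$i), trip$x) - 1L
  if (!length(words)) stop("dtm contains no tokens")
  set.seed(as.integer(seed))
  fit <- lda_gibbs_cpp(words, docs, nrow(dtm), ncol(dtm), as.integer(K),
                       alpha, beta, as.integer(n_iter), as.integer(burn_in))
  structure(list(
    K = as.integer(K),
    topic_word = matrix(fit$phi, K, ncol(dtm), dimnames = list(NULL, colnames(dtm))),
    doc_topic = matrix(fit$theta, nrow(dtm), K, dimnames = list(rownames(dtm), NULL)),
    alpha = alpha, beta = beta, seed = as.integer(seed),
    assignments = fit$assignments,
    loglik = fit$loglik, loglik_trace = fit$loglik_trace,
    vocab = colnames(dtm), doc_ids = rownames(dtm),
    doc_lengths = Matrix::rowSums(dtm)
  ), class = "lda_model")
}

#' @exportS3Method base::print
print.lda_model <- function(x, ...) {
  cat(sprintf("lda_model: K = %d topics over %d terms and %d documents (seed %d)\n",
              x$K, length(x$vocab), length(x$doc_ids), x$seed))
  invisible(x)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# harmonic-mean estimate of the marginal log-likelihood (maximize over K)
griffiths2004_metric <- function(loglik) {
  -(log_sum_exp(-loglik) - log(length(loglik)))
}

cosine_similarity <- function(p, q) sum(p * q) / sqrt(sum(p^2) * sum(q^2))

# mean pairwise cosine similarity among topic rows (minimize over K)
caojuan2009_metric <- function(topic_word) {
  K <- nrow(topic_word)
  if (K < 2) return(NA_real_)
  pairs <- utils::combn(K, 2)
  mean(apply(pairs, 2, function(ij)
    cosine_similarity(topic_word[ij[1], ], topic_word[ij[2], ])))
}

kl_divergence <- function(p, q) {
  s <- p > 0
  sum(p[s] * log(p[s] / q[s]))
}

#' Jensen-Shannon divergence between two distributions
#'
#' @param p,q Nonnegative vectors summing to 1.
#' @return `0.5 KL(p || m) + 0.5 KL(q || m)` with `m = (p + q) / 2`.
#' @export
jensen_shannon <- function(p, q) {
  m <- (p + q) / 2
  0.5 * kl_divergence(p, m) + 0.5 * kl_divergence(q, m)
}

# mean pairwise JS divergence among topic rows (maximize over K)
deveaud2014_metric <- function(topic_word) {
  K <- nrow(topic_word)
  if (K < 2) return(NA_real_)
  pairs <- utils::combn(K, 2)
  mean(apply(pairs, 2, function(ij)
    jensen_shannon(topic_word[ij[1], ], topic_word[ij[2], ])))
}

# symmetric KL between normalized singular values of topic_word and the
# length-weighted doc_topic marginal (minimize over K)
arun2010_metric <- function(topic_word, doc_topic, doc_lengths) {
  cm1 <- svd(topic_word)$d
  cm1 <- sort(cm1 / sum(cm1), decreasing = TRUE)
  cm2 <- as.numeric(doc_lengths %*% doc_topic)
  cm2 <- sort(cm2 / sum(cm2), decreasing = TRUE)
  kl_divergence(cm1, cm2) + kl_divergence(cm2, cm1)
}

#' Topic-number selection report
#'
#' Fits the Gibbs LDA at each candidate K and reports four standard
#' selection metrics: Griffiths2004 (harmonic-mean marginal log-likelihood;
#' maximize), CaoJuan2009 (mean pairwise topic cosine similarity; minimize),
#' Arun2010 (symmetric KL between singular-value and doc-topic marginals;
#' minimize) and Deveaud2014 (mean pairwise Jensen-Shannon divergence;
#' maximize).
#'
#' @param dtm Sparse document-term matrix.
#' @param k_candidates Integer vector of candidate topic counts (nonempty).
#' @param alpha `NULL` for the per-K default `50 / K`, or a fixed value.
#' @inheritParams fit_lda_gibbs
#' @return Tibble: K, griffiths2004, caojuan2009, arun2010, deveaud2014,
#'   with the fitted models attached as attribute `"models"`.
#' @export
select_k <- function(dtm, k_candidates, alpha = NULL, beta = 0.1,
                     n_iter = 500L, burn_in = n_iter %/% 2L, seed = 1L) {
  if (!length(k_candidates)) stop("k_candidates must be nonempty")
  models <- lapply(k_candidates, function(K) {
    fit_lda_gibbs(dtm, K, alpha = if (is.null(alpha)) 50 / K else alpha,
                  beta = beta, n_iter = n_iter, burn_in = burn_in, seed = seed)
  })
  out <- tibble(
    K = as.integer(k_candidates),
    griffiths2004 = vapply(models, function(m) griffiths2004_metric(m$loglik), numeric(1)),
    caojuan2009 = vapply(models, function(m) caojuan2009_metric(m$topic_word), numeric(1)),
    arun2010 = vapply(models, function(m)
      arun2010_metric(m$topic_word, m$doc_topic, m$doc_lengths), numeric(1)),
    deveaud2014 = vapply(models, function(m) deveaud2014_metric(m$topic_word), numeric(1))
  )
  attr(out, "models") <- models
  out
}
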