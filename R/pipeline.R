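#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [run_pipeline()]: exactly one of `synthetic:` (arguments of
#'   [synthetic_config()]) or `input:` (paths `corpus`, `format`, `users`,
#'   `emotion_lexicon`, `happiness_lexicon`), plus optional `emotions`,
#'   `lens_delta`, `topics:` (K, k_candidates, alpha, beta, n_iter, burn_in,
#'   tfidf_threshold, min_count, top_n, frex_weight, n_boot), `seed`,
#'   `out_dir`.
#' @return A `pipeline_config` list.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  pipeline_config(yaml::read_yaml(path))
}

#' Validate a pipeline configuration
#'
#' @param config Named list (see [load_pipeline_config()]).
#' @return The validated `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  has_syn <- !is.null(config$synthetic)
  has_inp <- !is.null(config$input)
  if (has_syn == has_inp)
    stop("exactly one of 'synthetic' or 'input' must be configured")
  defaults <- list(emotions = emotion_categories(), lens_delta = 0,
                   seed = 1L, out_dir = "emotopics_report", topics = list())
  topic_defaults <- list(K = 5L, k_candidates = NULL, alpha = NULL,
                         beta = 0.1, n_iter = 400L, burn_in = 200L,
                         tfidf_threshold = 0.1, min_count = 1L, top_n = 20L,
                         frex_weight = 0.5, n_boot = 500L)
  config <- modifyList(defaults, config)
  config$topics <- modifyList(topic_defaults, config$topics)
  structure(config, class = "pipeline_config")
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage:%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on either a synthetic corpus or files on disk:
#' cleaning, cohort summary, emotion table and gender comparisons, monthly
#' emotion series, daily happiness series, DTM construction with TF-IDF
#' filtering, optional topic-number selection, LDA fitting, topic profiles,
#' diagnostics, gender-prevalence effects, topic correlations and topic
#' happiness analysis. All tables are written as TSV (plus a JSON report and
#' a run manifest) under `out_dir`; reruns with the same config and seed are
#' bit-identical.
#'
#' @param config A `pipeline_config`, a list coercible to one, or a YAML
#'   path.
#' @return Invisibly, a list with the computed objects and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # pre-flight: every configured input must exist before any computation
  stage("preflight", {
    if (!is.null(config$input)) {
      paths <- unlist(config$input[c("corpus", "users", "emotion_lexicon",
                                     "happiness_lexicon")])
      missing <- paths[!file.exists(paths)]
      if (length(missing))
        stop("missing input file(s): ", paste(missing, collapse = ", "))
    }
  })

  inputs <- stage("load", {
    if (!is.null(config$synthetic)) {
      syn_args <- config$synthetic
      if (is.null(syn_args$seed)) syn_args$seed <- config$seed
      gen <- generate_corpus(do.call(synthetic_config, syn_args))
      list(corpus = gen$corpus, emo = gen$emotion_lexicon,
           hap = gen$happiness_lexicon, truth = gen$ground_truth)
    } else {
      list(corpus = load_corpus(config$input$corpus,
                                format = config$input$format %||% "jsonl",
                                users = config$input$users),
           emo = load_emotion_lexicon(config$input$emotion_lexicon),
           hap = load_happiness_lexicon(config$input$happiness_lexicon),
           truth = NULL)
    }
  })
  corpus <- inputs$corpus
  if (any(vapply(corpus$tweets$tokens, is.null, logical(1))))
    corpus <- stage("clean", clean_corpus(corpus))

  cohort <- stage("cohort", summarize_cohort(corpus))
  write_tsv(cohort$per_gender, file.path(out_dir, "cohort_summary.tsv"))

  emo_table <- stage("emotions", build_emotion_table(corpus, inputs$emo))
  write_tsv(emo_table, file.path(out_dir, "emotion_table.tsv"))
  comparisons <- stage("emotions", compare_groups(corpus, inputs$emo, config$emotions))
  write_tsv(comparisons, file.path(out_dir, "emotion_comparisons.tsv"))
  monthly <- stage("emotions", monthly_series(corpus, inputs$emo, config$emotions))
  write_tsv(monthly, file.path(out_dir, "monthly_emotions.tsv"))

  daily <- stage("happiness", daily_series(corpus, inputs$hap, config$lens_delta))
  write_tsv(daily, file.path(out_dir, "daily_happiness.tsv"))

  tc <- config$topics
  topic_out <- stage("topics", {
    gender <- corpus$users$gender[match(corpus$tweets$user_id, corpus$users$user_id)]
    keep <- gender %in% c("woman", "man")
    sub <- corpus
    sub$tweets <- sub$tweets[keep, ]
    dtm <- build_dtm(sub, min_count = tc$min_count)
    dtm <- tfidf_filter(dtm, tc$tfidf_threshold)
    ksel <- NULL
    if (!is.null(tc$k_candidates)) {
      ksel <- select_k(dtm, tc$k_candidates, alpha = tc$alpha, beta = tc$beta,
                       n_iter = tc$n_iter, burn_in = tc$burn_in,
                       seed = config$seed)
      write_tsv(as.data.frame(ksel), file.path(out_dir, "k_selection.tsv"))
    }
    model <- fit_lda_gibbs(dtm, tc$K,
                           alpha = if (is.null(tc$alpha)) 50 / tc$K else tc$alpha,
                           beta = tc$beta, n_iter = tc$n_iter,
                           burn_in = tc$burn_in, seed = config$seed)
    doc_gender <- gender[keep][match(model$doc_ids, sub$tweets$tweet_id)]
    profiles <- label_topics(model, n = min(tc$top_n, length(model$vocab)),
                             frex_weight = tc$frex_weight)
    diagnostics <- topic_diagnostics(model, dtm)
    prevalence <- estimate_prevalence(model, doc_gender, n_boot = tc$n_boot,
                                      seed = config$seed)
    correlations <- topic_correlations(model)
    happiness <- topic_happiness_analysis(profiles, prevalence, inputs$hap)
    write_tsv(profiles, file.path(out_dir, "topic_profiles.tsv"))
    write_tsv(diagnostics, file.path(out_dir, "topic_diagnostics.tsv"))
    write_tsv(prevalence, file.path(out_dir, "topic_prevalence.tsv"))
    write_tsv(as.data.frame(correlations), file.path(out_dir, "topic_correlations.tsv"))
    write_tsv(happiness$per_topic, file.path(out_dir, "topic_happiness.tsv"))
    write_tsv(happiness$pairwise, file.path(out_dir, "topic_happiness_pairwise.tsv"))
    list(dtm = dtm, k_selection = ksel, model = model, profiles = profiles,
         diagnostics = diagnostics, prevalence = prevalence,
         correlations = correlations, happiness = happiness)
  })

  stage("report", {
    report <- list(
      seed = config$seed,
      cohort_overall = cohort$overall[c("n_users", "collected_tweets",
                                        "lifetime_tweets", "collected_fraction_pct",
                                        "geolocated_users", "geolocated_pct")],
      happiness_regression = topic_out$happiness$regression)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg_path <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(unclass(config), cfg_path)
    # hash the config with location-dependent fields stripped, so reruns of
    # the same analysis in different directories carry the same fingerprint
    canon <- unclass(config)
    canon$out_dir <- NULL
    canon_path <- tempfile(fileext = ".yaml")
    yaml::write_yaml(canon, canon_path)
    cfg_md5 <- unname(tools::md5sum(canon_path))
    unlink(canon_path)
    manifest <- list(
      seed = config$seed,
      config_md5 = cfg_md5,
      package_version = as.character(utils::packageVersion("emotopics")),
      n_tweets = nrow(corpus$tweets), n_users = nrow(corpus$users))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  invisible(list(out_dir = out_dir, corpus = corpus, cohort = cohort,
                 emotion_table = emo_table, comparisons = comparisons,
                 monthly = monthly, daily = daily, topics = topic_out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
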