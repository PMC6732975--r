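---
title: "Methods: gender-stratified emotion, happiness and topic analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gender-stratified emotion, happiness and topic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emotopics)
```

This vignette is the package's own account of the statistical procedures it
implements, the assumptions behind them, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical and design choices made where the methods literature leaves
the design open.

## The analysis problem

Patient communities on microblogging platforms leave a continuous record of
spontaneously expressed emotion. The package targets study designs that
compare two author groups — here labelled *woman* and *man*, from manually
coded profile metadata — across three complementary views of the same
corpus:

1. **Lexicon emotion counting**: how often words associated with each of
   Plutchik's eight emotions (plus the positive/negative polarities) occur,
   overall and per tweet;
2. **Happiness scoring**: crowd-rated per-word happiness averaged over
   tweets, days and word sets;
3. **Topic structure**: what the groups talk about, which topics lean
   toward which group, and how topic content relates to happiness.

All three are bag-of-words methods. They assume that group differences in
word usage reflect group differences in expressed emotion; they do not
model negation, sarcasm or context (a "not happy" tweet contributes a
*happy* token). This limitation is inherited from the underlying lexicons
and is shared by the study designs the package supports.

## Text normalization

`clean_text()` applies a fixed, deterministic order: lowercase; mention
normalization (`@somebody` → the literal token `@user`); URL removal;
punctuation removal; non-printable/emoji removal; whitespace tokenization;
stopword removal; table-driven lemmatization. The order matters in two
places and was fixed deliberately:

* mentions are normalized **before** punctuation stripping so the `@` of
  `@user` survives as part of the token — author references remain
  countable without identifying anyone;
* URLs are removed **before** punctuation stripping so they disappear
  whole instead of shedding word-like fragments.

Apostrophes are deleted (so *dog's* → *dogs* → lemma *dog*) while other
punctuation becomes a token boundary (so *well-known* → *well*, *known*).
Hashtags keep their text with `#` stripped, since their content is
analyzable. Emoji are removed, not scored.

Lemmatization is a pure table lookup (`default_lemma_table()` ships a small
starter table; serious analyses should supply a fuller one). A statistical
lemmatizer would cover more forms but would make results depend on model
versions; the table keeps the pipeline bit-for-bit reproducible. The
stopword list is likewise an input artifact. The packaged default is a
Snowball-style list normalized the same way tokens are; contractions whose
apostrophe-stripped forms collide with content words (*we'll* → *well*,
*he'll* → *hell*, *she'd* → *shed*, ...) were removed from the list so the
collision cannot silently delete real words. Duplicate tweets are kept:
deduplication is left to the caller because retweet conventions vary by
platform and study.

## Emotion scoring and the per-tweet proportion

`score_emotions()` adds 1 to every category a token's form maps to; a word
may carry several categories (NRC-style lexicons attach both an emotion and
a polarity to many words). The per-tweet statistic is

$$\mathrm{proportion}_X = \frac{n_X}{n_{\mathrm{negative}} + n_{\mathrm{positive}}}$$

which tracks the *share* of sentiment-bearing words expressing emotion
$X$, making tweets of different lengths comparable and bounding the
positive/negative proportions in $[0,1]$ with
$\mathrm{proportion}_{pos} + \mathrm{proportion}_{neg} = 1$ whenever
defined. Tweets with a zero denominator are **excluded** from comparisons
rather than imputed: the statistic is simply undefined there, and imputing
0 would manufacture mass at the boundary. Group comparisons therefore run
on per-tweet values (not per-user means) — the reporting unit of the
downstream tests is the tweet, which matches the very large rank-sum
statistics such designs report, but means tweets from prolific users weigh
more; a per-user robustness check is easy to run on top of
`corpus_emotion_proportions`-derived tables.

Two tests are computed per emotion. The variance-ratio test
$F = s^2_x / s^2_y$ (sample variances, two-sided p) checks variance
homogeneity; since proportions are bounded and zero-inflated, homogeneity
usually fails, and the rank-sum test is the primary comparison. `W` is the
Mann–Whitney $U$ of the women sample over the men sample (ties count ½),
and p uses the normal approximation with tie correction and continuity
correction. The approximation is the right tool at corpus scale (thousands
of tweets); at toy sizes ($n, m \le 7$) it can deviate from the exact
permutation p by up to about 0.09, which the test suite bounds explicitly
against an exhaustive enumeration oracle.

## Happiness scoring

`tweet_happiness()` is the frequency-weighted mean of matched word scores,
so duplicating the token list leaves it unchanged and every value lies
between the minimum and maximum matched score. The *lens* parameter
`lens_delta` excludes words with $|h(w) - 5| < \delta$ before averaging;
the default is `0` (no exclusion). The hedonometer literature often uses
$\delta = 1$ to sharpen signal, but topic-level summaries in this package
score mid-scale clinical vocabulary (e.g. *stroke*, $h = 2.58$, but also
many ~5.0 words) and the package's reference analyses include them, so
exclusion is opt-in rather than default.

`daily_series()` pools at the **word** level within each (UTC day, gender)
cell — the day mean is the mean of all matched word scores that day, not a
mean of tweet means — so long tweets contribute proportionally to their
word count. A `per_user = TRUE` variant first averages within each user's
day and then across users, for designs that want users weighted equally;
both are exposed because published descriptions of daily summaries are
often ambiguous between the two.

## Document-term matrix and TF-IDF pruning

`build_dtm()` produces a sparse documents × vocabulary count matrix with a
lexicographically sorted vocabulary (determinism) and no all-zero columns.
`tfidf_filter()` scores each term as the mean, over documents containing
it, of $\frac{c_{dt}}{\ell_d}\log_2\frac{D}{df_t}$ and removes terms at or
below the threshold (default 0.1). Base-2 logs and mean-over-containing-
documents aggregation are one of several TF-IDF variants in circulation;
this one makes the score of a ubiquitous term exactly 0 (it is always
removed) and is cheap on sparse matrices. Documents emptied by pruning are
dropped with a message, since downstream samplers need tokens.

## Collapsed-Gibbs LDA

`fit_lda_gibbs()` implements the standard collapsed Gibbs sampler over
token-topic assignments with symmetric priors (defaults $\alpha = 50/K$,
$\beta = 0.1$ — the classic settings). `topic_word` and `doc_topic` are
posterior means averaged over every post-burn-in sweep, then renormalized
so rows sum to 1 within $10^{-9}$. The sampler runs in C++ but draws all
randomness from R's RNG, so a seed makes the entire fit — including the
final token assignments — bit-reproducible. Defaults are `n_iter = 500`
with half discarded as burn-in; the integrated log-likelihood
$\log p(w \mid z)$ is recorded every sweep so chains can be inspected
(its trend is monitored on planted corpora, not strictly asserted, since
Gibbs trajectories are not monotone). Documents with no tokens receive the
prior-mean (uniform) topic distribution.

Note one consequence of posterior-mean shrinkage: with $\alpha = 50/K$ and
30-token documents, the estimated `doc_topic` is pulled strongly toward
uniform, so group differences in *estimated* prevalence are attenuated
relative to the planted generative difference. Labels and signs are
preserved — which is what the prevalence analysis reports — but effect
magnitudes on the $\theta$ scale should not be read as generative effect
sizes.

## Topic-number selection

`select_k()` reports four standard diagnostics per candidate $K$:
Griffiths2004 (harmonic-mean estimate of the marginal log-likelihood over
kept sweeps; maximize), CaoJuan2009 (mean pairwise cosine similarity of
topic rows; minimize), Arun2010 (symmetric KL divergence between the
normalized singular values of `topic_word` and the length-weighted
`doc_topic` marginal; minimize) and Deveaud2014 (mean pairwise
Jensen–Shannon divergence of topic rows; maximize). The function informs
but does not auto-pick: the diagnostics routinely disagree (the harmonic-
mean estimator in particular keeps rising with $K$ on short documents),
and the final $K$ is a modelling decision the analyst records in the
pipeline config.

## The covariate surrogate for structural topic models

A full structural topic model ties document covariates into estimation
through a logistic-normal prior fitted by variational EM. This package
deliberately uses a simpler, fully specifiable surrogate with the same
reportable outputs:

* **Prevalence**: `estimate_prevalence()` contrasts posterior-mean topic
  shares, $\mathrm{effect}_k = \bar\theta_{k,\text{women}} -
  \bar\theta_{k,\text{men}}$, with a stratified nonparametric bootstrap
  over documents (resampling within each gender, 1000 replicates by
  default) and percentile CIs. A topic is labelled *more likely women* or
  *more likely men* only when the 95% CI excludes 0. Effects sum to zero
  across topics by compositionality.
* **Correlations**: `topic_correlations()` applies the centered-log-ratio
  transform to `doc_topic` rows and takes Pearson correlations across
  documents — the natural compositional surrogate for the logistic-normal
  covariance. With $K = 2$ the off-diagonal is forced to $-1$ by closure,
  a reminder that these are correlations of *shares*.
* **Word profiles**: `label_topics()` ranks words by probability, by FREX
  (the weighted harmonic mean of the within-topic empirical-CDF ranks of
  exclusivity and probability, weight 0.5 on exclusivity by default) and
  by the term score $\phi_{kv}(\log\phi_{kv} - \frac1K\sum_j
  \log\phi_{jv})$. Ties break lexicographically. At $K = 1$ the score is
  identically zero (the ordering degenerates to the lexicographic
  tie-break), so only the probability and FREX orderings are meaningful
  there. A literal "ratio of log frequencies" formulation of the score is
  numerically ill-behaved near zero probabilities and was rejected in
  favour of the standard form above.
* **Diagnostics**: Mimno semantic coherence
  $\sum_{i=2}^{M}\sum_{j<i}\log\frac{D(v_i,v_j)+1}{D(v_j)}$ over each
  topic's top-$M$ words (default 10), plus a top-word exclusivity mean in
  $[0,1]$.

`topic_happiness_analysis()` then scores each topic's top
highest-probability words with the happiness lexicon, orders topics by
their prevalence effect (rank 1 = most-men, rank $K$ = most-women),
regresses word-level scores on topic rank (two-sided slope test) and
compares every topic pair's word scores with the rank-sum test. The
regression's observation unit is the *word*, the only unit available once
topics are reduced to word lists; a flat score vector is flagged with
slope 0 and $p = 1$ rather than an undefined fit.

## The synthetic-data generator

`generate_corpus()` emulates exactly the statistical structure the
analyses assume, with every planted parameter recorded:

* two user groups of `n_users` each (default 200) posting
  `tweets_per_user` tweets (default 50) with timestamps uniform over
  2007-08-01 – 2018-12-01;
* per-token emotion emission: with probability $\pi(g, c)$ a token is
  drawn uniformly from category $c$'s word list. The default rates plant
  women elevated on joy/trust/anticipation/positive and men elevated on
  fear/sadness/disgust/negative (per-gender totals ≈ 0.41), the effect
  directions this study design expects. Emotion words from the positive-
  pole emotions also carry the *positive* polarity tag (negative-pole
  likewise), mirroring NRC structure and keeping the proportion
  denominator populated; *surprise* words carry no polarity;
* remaining tokens come from `K_true` planted topics (default 5): document
  topic shares are Dirichlet with concentration 10 around gender-specific
  means that give topic 1 a +0.10 woman−man prevalence gap by default,
  and each topic's word distribution puts 80% of its mass on its own
  40-word block (Dirichlet(5) within the block) and 20% on shared neutral
  fillers;
* happiness scores are drawn per word around category profiles (positive
  pole ≈ 7, negative pole ≈ 3, neutral ≈ 5, SD 0.5, clamped to [1, 9]),
  mimicking the empirical alignment between emotion lexicons and
  happiness ratings;
* token counts per tweet are Poisson(12) (or constant, for fixtures), and
  everything — vocabulary, users, countries, list memberships,
  timestamps, tokens — derives deterministically from one seed.

Emotion and topic vocabularies are disjoint by default so emotion-recovery
and topic-recovery tests cannot confound each other. What the generator
does **not** emulate: real word frequency distributions (Zipf tails),
grammar, negation, retweet/duplicate structure, bursty posting dynamics,
or users who change style over time. Passing recovery tests therefore
demonstrates that the estimators detect the effects they target at
realistic sizes and calibrate correctly under the null — not that any
particular real-world corpus satisfies the generative assumptions.

## Cohort summaries

`select_members()` applies the list-membership inclusion rule (a user must
appear in at least `min_lists` curated lists, default 3, counted over
distinct lists). `cohort_summary()` reproduces the usual sample-description
arithmetic with fixed rounding conventions: mean tweets/user to the nearest
integer, collected-tweet fractions to 1 decimal, geolocation and country
percentages to 2 decimals (both configurable). Users with unknown gender
are excluded from the gender-stratified rows but counted in overall
totals, since stratified analyses run only on coded genders.

## Numerical choices and degenerate inputs

* Probabilities are floored at $10^{-300}$ before logs (CLR, term score).
* The proportion statistic returns `NA` (never an error) on a zero
  denominator; comparisons drop `NA`s and flag an emotion *untestable*
  when a group has no defined values.
* `variance_ratio_test` refuses a zero-variance second sample;
  `rank_sum_test` returns $p = 1$ when all values tie.
* Zero-variance CLR columns yield correlation 0 with a warning; the
  diagonal is forced to exactly 1.
* All word rankings break ties lexicographically, so outputs are stable
  across platforms.
* Lexicon loaders validate hard: unknown category names, non-binary
  association flags, conflicting duplicate lines and out-of-range
  happiness scores are errors naming the offending entry, because silent
  lexicon corruption is the classic failure mode of these pipelines.

## Problem sizes used by the test suite

The suite validates recovery at sizes chosen to be decisive yet quick: the
joy-excess power setting uses 200 users/gender × 50 tweets over 20 seeds;
topic recovery uses the standard fixture (vocabulary 200, $K = 5$, 1000
documents, 30 tokens each) with 400 Gibbs sweeps; prevalence-label
recovery repeats that fixture over 20 seeds; null calibration uses 100
replicates of 50 users/gender × 20 tweets. Oracle-equivalence checks run
on randomized toy inputs against brute-force reimplementations
(enumeration for the rank-sum test, double loops for scoring, tallying,
TF-IDF and coherence).

## Orchestration

`run_pipeline()` drives all stages from a single validated config (R list
or YAML), writes every table as TSV plus a JSON report, and records a run
manifest with the seed and a config fingerprint that is invariant to the
output location, so a report can be regenerated bit-identically from its
manifest. The package exposes each stage as an ordinary function rather
than a shell subcommand interface: an R analysis package is driven from R,
and the YAML config plus `Rscript -e` covers scripted use.

## Known limitations

* Bag-of-words only; no negation or valence shifting.
* The lemma table is small by default; unlisted inflections pass through
  unlemmatized.
* The prevalence surrogate contrasts posterior means; it does not
  propagate topic-assignment uncertainty into the bootstrap, and
  posterior-mean shrinkage attenuates effect magnitudes (labels and signs
  are unaffected).
* The topic-happiness regression treats words as independent
  observations; words shared between topics are counted once per topic.
* Emotion categories are treated independently; a word may legitimately
  contribute to several.
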