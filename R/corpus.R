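#' Construct a tweet corpus
#'
#' Bundles a tweet table and a user metadata table into a validated corpus
#' object. Every tweet must reference exactly one known user; unknown
#' references are a referential-integrity error.
#'
#' @param tweets Data frame with columns `tweet_id`, `user_id`, `timestamp`
#'   (POSIXct, UTC) and `text`. An optional `tokens` list-column holds the
#'   cleaned token sequences.
#' @param users Data frame with columns `user_id`, `gender` (one of
#'   `"woman"`, `"man"`, `"unknown"`) and optionally `country` (ISO-3166
#'   code or NA), `lifetime_tweet_count`, `follower_count` and
#'   `list_memberships` (list-column of list identifiers). Missing optional
#'   columns are filled with defaults.
#' @return An object of class `tweet_corpus`: a list with elements `tweets`
#'   and `users` (tibbles).
#' @export
tweet_corpus <- function(tweets, users = NULL) {
  tweets <- as_tibble(tweets)
  required <- c("tweet_id", "user_id", "timestamp", "text")
  missing_cols <- setdiff(required, names(tweets))
  if (length(missing_cols))
    stop("tweet table is missing required field(s): ",
         paste(missing_cols, collapse = ", "))
  tweets$tweet_id <- as.character(tweets$tweet_id)
  tweets$user_id <- as.character(tweets$user_id)
  if (!inherits(tweets$timestamp, "POSIXct"))
    tweets$timestamp <- parse_utc(tweets$timestamp)
  attr(tweets$timestamp, "tzone") <- "UTC"
  tweets$text <- as.character(tweets$text)
  if (!"tokens" %in% names(tweets))
    tweets$tokens <- replicate(nrow(tweets), NULL, simplify = FALSE)

  if (is.null(users)) {
    counts <- table(tweets$user_id)
    users <- tibble(
      user_id = as.character(if (length(counts)) names(counts) else character(0)),
      gender = rep("unknown", length(counts)),
      lifetime_tweet_count = as.integer(counts)
    )
  }
  users <- as_tibble(users)
  if (!"user_id" %in% names(users))
    stop("user table is missing required field(s): user_id")
  users$user_id <- as.character(users$user_id)
  if (!"gender" %in% names(users)) users$gender <- "unknown"
  bad_gender <- setdiff(unique(users$gender), c("woman", "man", "unknown"))
  if (length(bad_gender))
    stop("invalid gender value(s): ", paste(bad_gender, collapse = ", "),
         " (must be woman, man or unknown)")
  if (!"country" %in% names(users)) users$country <- NA_character_
  collected <- table(factor(tweets$user_id, levels = users$user_id))
  if (!"lifetime_tweet_count" %in% names(users))
    users$lifetime_tweet_count <- as.integer(collected)
  if (!"follower_count" %in% names(users)) users$follower_count <- 0L
  if (!"list_memberships" %in% names(users))
    users$list_memberships <- replicate(nrow(users), character(0), simplify = FALSE)

  if (anyDuplicated(users$user_id))
    stop("duplicate user_id in user table")
  orphan <- setdiff(unique(tweets$user_id), users$user_id)
  if (length(orphan))
    stop("referential-integrity error: tweet user_id(s) not in user table: ",
         paste(head(orphan, 5), collapse = ", "))
  if (any(users$lifetime_tweet_count < as.integer(collected)))
    stop("lifetime_tweet_count below number of collected tweets for user(s): ",
         paste(head(users$user_id[users$lifetime_tweet_count < as.integer(collected)], 5),
               collapse = ", "))

  structure(list(tweets = tweets, users = users), class = "tweet_corpus")
}

parse_utc <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  out
}

#' @exportS3Method base::print
print.tweet_corpus <- function(x, ...) {
  ng <- table(factor(x$users$gender, levels = c("woman", "man", "unknown")))
  cleaned <- sum(!vapply(x$tweets$tokens, is.null, logical(1)))
  cat(sprintf("tweet_corpus: %d tweets from %d users (%d women, %d men, %d unknown)\n",
              nrow(x$tweets), nrow(x$users), ng[["woman"]], ng[["man"]],
              ng[["unknown"]]))
  cat(sprintf("  cleaned tokens present for %d/%d tweets\n", cleaned, nrow(x$tweets)))
  invisible(x)
}

#' Load a corpus from disk
#'
#' Reads tweets from a JSON-lines file (one object per tweet with fields
#' `tweet_id`, `user_id`, `timestamp` ISO-8601 UTC, `text`) or a delimited
#' table with the same columns, plus an optional user metadata table
#' (CSV/TSV). Row order is preserved.
#'
#' @param path Path to the tweet file.
#' @param format `"jsonl"` or `"delimited"` (TSV/CSV, sniffed from the header
#'   line).
#' @param users Optional user data frame, or path to a delimited user table.
#' @return A [tweet_corpus()].
#' @export
load_corpus <- function(path, format = c("jsonl", "delimited"), users = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      tweets <- tibble(tweet_id = character(0), user_id = character(0),
                       timestamp = as.POSIXct(character(0), tz = "UTC"),
                       text = character(0))
    } else {
      tweets <- jsonlite::stream_in(textConnection(lines), verbose = FALSE)
      tweets <- as_tibble(tweets)
    }
  } else {
    tweets <- read_delim_auto(path)
  }
  required <- c("tweet_id", "user_id", "timestamp", "text")
  missing_cols <- setdiff(required, names(tweets))
  if (length(missing_cols))
    stop("corpus file is missing required field(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.character(users)) users <- read_user_table(users)
  tweet_corpus(tweets, users)
}

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  as_tibble(read.delim(path, sep = sep, stringsAsFactors = FALSE,
                       colClasses = "character"))
}

#' Read a user metadata table
#'
#' @param path Delimited (CSV/TSV) file with at least a `user_id` column;
#'   `list_memberships` may be given as a `|`-separated string.
#' @return Tibble of user records.
#' @export
read_user_table <- function(path) {
  if (!file.exists(path)) stop("user table not found: ", path)
  users <- read_delim_auto(path)
  if ("lifetime_tweet_count" %in% names(users))
    users$lifetime_tweet_count <- as.integer(users$lifetime_tweet_count)
  if ("follower_count" %in% names(users))
    users$follower_count <- as.integer(users$follower_count)
  if ("list_memberships" %in% names(users) &&
      is.character(users$list_memberships))
    users$list_memberships <- strsplit(users$list_memberships, "|", fixed = TRUE)
  users
}

#' Write a corpus to disk
#'
#' Writes tweets as JSON-lines or a delimited table, and optionally the user
#' table as TSV. Inverse of [load_corpus()] for valid corpora.
#'
#' @param corpus A `tweet_corpus`.
#' @param path Output path for tweets.
#' @param format `"jsonl"` or `"delimited"`.
#' @param users_path Optional output path for the user table (TSV).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "delimited"),
                         users_path = NULL) {
  format <- match.arg(format)
  tw <- corpus$tweets
  out <- data.frame(
    tweet_id = tw$tweet_id, user_id = tw$user_id,
    timestamp = format(tw$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    text = tw$text, stringsAsFactors = FALSE)
  if (format == "jsonl") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    jsonlite::stream_out(out, con, verbose = FALSE)
  } else {
    write.table(out, path, sep = "\t", row.names = FALSE, quote = TRUE)
  }
  if (!is.null(users_path)) {
    us <- corpus$users
    us$list_memberships <- vapply(us$list_memberships, paste, character(1),
                                  collapse = "|")
    write.table(us, users_path, sep = "\t", row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}
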