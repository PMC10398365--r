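#' Read forum posts from a JSON Lines dump
#'
#' One post per line. Required fields: `forum`, `author`, `created_utc`,
#' `title`; optional: `body` (missing or null becomes the empty string,
#' i.e. an image-only post) and `abstinence_days` (self-reported days since
#' last use). Malformed lines (unparseable JSON or missing required fields)
#' are skipped and counted; more than 5% malformed lines is an error.
#'
#' @param path Path to a JSONL file (UTF-8).
#' @param max_malformed_frac Error threshold for the fraction of skipped
#'   lines. Default `0.05`.
#' @param quiet Suppress the skipped-line message.
#'
#' @return A tibble with columns `forum`, `author`, `created_utc`, `title`,
#'   `body`, `abstinence_days` and attribute `n_malformed`.
#' @export
read_posts_jsonl <- function(path, max_malformed_frac = 0.05, quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("cannot read posts file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(paste0("posts file is empty: ", path))

  required <- c("forum", "author", "created_utc", "title")
  parse_one <- function(ln) {
    rec <- tryCatch(jsonlite::fromJSON(ln), error = function(e) NULL)
    if (is.null(rec) || !is.list(rec)) return(NULL)
    if (!all(required %in% names(rec))) return(NULL)
    tibble(
      forum = as.character(rec$forum),
      author = as.character(rec$author),
      created_utc = as.numeric(rec$created_utc),
      title = as.character(rec$title %||% ""),
      body = as.character(rec$body %||% ""),
      abstinence_days = if (is.null(rec$abstinence_days)) NA_real_ else
        as.numeric(rec$abstinence_days)
    )
  }
  parsed <- lapply(lines, parse_one)
  bad <- vapply(parsed, is.null, logical(1))
  n_bad <- sum(bad)
  if (n_bad / length(lines) > max_malformed_frac) {
    abort(sprintf("%d of %d lines malformed in %s (over %.0f%% threshold)",
                  n_bad, length(lines), path, 100 * max_malformed_frac))
  }
  if (n_bad > 0L && !quiet) {
    inform(sprintf("read_posts_jsonl: skipped %d malformed line(s) of %d",
                   n_bad, length(lines)))
  }
  out <- dplyr::bind_rows(parsed[!bad])
  out$body[is.na(out$body)] <- ""
  attr(out, "n_malformed") <- n_bad
  out
}

#' Write posts to JSON Lines
#'
#' Emits the same dialect [read_posts_jsonl()] reads. `abstinence_days`
#' is omitted from records where it is `NA`.
#'
#' @param posts A posts tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_posts_jsonl <- function(posts, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  has_abs <- "abstinence_days" %in% names(posts)
  for (i in seq_len(nrow(posts))) {
    rec <- list(
      forum = posts$forum[i], author = posts$author[i],
      created_utc = posts$created_utc[i], title = posts$title[i],
      body = posts$body[i]
    )
    if (has_abs && !is.na(posts$abstinence_days[i])) {
      rec$abstinence_days <- posts$abstinence_days[i]
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Keep only posts with body text
#'
#' A post counts as textual when its body yields at least one token after
#' normalisation, so whitespace- or punctuation-only bodies are treated as
#' image-only and dropped. Idempotent; preserves post order.
#'
#' @param posts A posts tibble.
#' @return The filtered tibble.
#' @export
filter_text_posts <- function(posts) {
  if (nrow(posts) == 0L) return(posts)
  toks <- preprocess_text(posts$body, collapse = FALSE)
  dplyr::filter(posts, lengths(toks) >= 1L)
}

#' Does a forum's extraction window pass the text-density inclusion filter?
#'
#' Forums are extracted as a fixed window of consecutive posts; a forum is
#' included only if at least `min_text` of those posts are textual. The
#' filter is defined on the fixed window, so the original window size must
#' match `window`.
#'
#' @param posts The forum's extracted posts (before or after text
#'   filtering).
#' @param min_text Minimum number of textual posts. Default 3000.
#' @param window Required extraction window size. Default 5025.
#' @param window_size Number of posts originally extracted; defaults to the
#'   `window_size` attribute of `posts`, else `nrow(posts)`.
#' @return `TRUE` or `FALSE`.
#' @export
passes_inclusion <- function(posts, min_text = 3000, window = 5025,
                             window_size = NULL) {
  window_size <- window_size %||% attr(posts, "window_size") %||% nrow(posts)
  if (window_size != window) {
    abort(sprintf(
      "inclusion filter is defined on a %d-post window; corpus window is %d",
      window, window_size))
  }
  nrow(filter_text_posts(posts)) >= min_text
}

#' Keep the n most recent posts
#'
#' Retains the `n` posts with the largest `created_utc`. Timestamp ties at
#' the boundary are broken by input order (earlier rows win), and the
#' result preserves the input's relative order, so the output is always a
#' subsequence of the input.
#'
#' @param posts A posts tibble (typically already filtered to text posts).
#' @param n Number of posts to keep. Default 3003.
#' @return A tibble of exactly `n` posts.
#' @export
truncate_recent <- function(posts, n = 3003) {
  if (nrow(posts) < n) {
    abort(sprintf("cannot keep %d most recent posts: only %d available (short by %d)",
                  n, nrow(posts), n - nrow(posts)))
  }
  keep <- order(-posts$created_utc, seq_len(nrow(posts)))[seq_len(n)]
  posts[sort(keep), , drop = FALSE]
}

#' Count distinct post authors
#'
#' @param posts A posts tibble.
#' @param deleted_sentinel Author string marking deleted accounts, excluded
#'   from the count. Default `"[deleted]"`.
#' @return Integer count of distinct authors.
#' @export
count_unique_authors <- function(posts, deleted_sentinel = "[deleted]") {
  length(setdiff(unique(posts$author), deleted_sentinel))
}

#' Parse an abstinence badge string into days
#'
#' Optional helper for dumps where abstinence is a flair string such as
#' `"42 days"` rather than a numeric field. Not applied automatically.
#'
#' @param x Character vector of flair strings.
#' @return Numeric days (`NA` where no leading number is found).
#' @export
parse_abstinence_flair <- function(x) {
  m <- regmatches(x, regexpr("[0-9]+(\\.[0-9]+)?", x))
  out <- rep(NA_real_, length(x))
  out[regexpr("[0-9]", x) > 0] <- as.numeric(m)
  out
}
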