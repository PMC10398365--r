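#' Count lexicon matches in a token stream
#'
#' For each lexicon category, counts the tokens belonging to that
#' category's word set. A token appearing in m categories increments all m
#' counts. The sum over categories is the stream's lexicon match total (the
#' "emotion score" when the lexicon is the emotion bank).
#'
#' @param tokens Character vector of normalised tokens (see
#'   [preprocess_text()]).
#' @param lex A [lexicon()].
#' @return A tibble with columns `category` (in lexicon order) and `count`,
#'   with attribute `total`.
#' @export
count_matches <- function(tokens, lex) {
  stopifnot(inherits(lex, "cessalex_lexicon"))
  cats <- lexicon_categories(lex)
  hits <- tokens[tokens %in% lex$word]
  tab <- table(hits)
  per_word <- as.integer(tab[lex$word])
  per_word[is.na(per_word)] <- 0L
  counts <- as.integer(rowsum(per_word, factor(lex$category, levels = cats)))
  out <- tibble(category = cats, count = counts)
  attr(out, "total") <- sum(counts)
  attr(out, "lex_name") <- attr(lex, "lex_name")
  out
}

# Pool one token stream per forum from the chosen text field(s).
tokens_by_forum <- function(posts, field = c("body", "title_body")) {
  field <- match.arg(field)
  text <- if (field == "body") posts$body else paste(posts$title, posts$body)
  split(preprocess_text(text, collapse = FALSE), posts$forum) |>
    lapply(unlist, use.names = FALSE)
}

#' Normalised occurrence-frequency profile of one or more forum corpora
#'
#' Counts are pooled over all of a forum's posts and normalised once by the
#' forum's total lexicon matches, giving a percentage per category that
#' sums to 100. Each forum is profiled independently.
#'
#' @param posts A posts tibble (one or more forums).
#' @param lex A [lexicon()].
#' @param field Which text feeds the counts: `"body"` (default) or
#'   `"title_body"`.
#' @return A tibble of class `cessalex_profile` with columns `forum`,
#'   `category` (lexicon order within forum), `count`, `frequency`
#'   (percent), and attributes `lex_name`, `categories`, `field`, `totals`
#'   (named per-forum match totals).
#' @export
corpus_profile <- function(posts, lex, field = c("body", "title_body")) {
  stopifnot(inherits(lex, "cessalex_lexicon"))
  field <- match.arg(field)
  if (nrow(posts) == 0L) abort("cannot profile an empty corpus")
  toks <- tokens_by_forum(posts, field)
  profs <- purrr::imap(toks, function(tk, forum) {
    cm <- count_matches(tk, lex)
    total <- attr(cm, "total")
    if (total == 0L) {
      abort(paste0("no lexicon matches in corpus for forum ", forum))
    }
    tibble(forum = forum, category = cm$category, count = cm$count,
           frequency = 100 * cm$count / total)
  })
  out <- dplyr::bind_rows(profs)
  totals <- vapply(profs, function(p) sum(p$count), numeric(1))
  new_profile(out, lex, field, totals)
}

new_profile <- function(df, lex, field, totals) {
  structure(
    as_tibble(df),
    lex_name = attr(lex, "lex_name"),
    categories = lexicon_categories(lex),
    field = field,
    totals = totals,
    class = c("cessalex_profile", class(as_tibble(df)))
  )
}

#' @export
print.cessalex_profile <- function(x, ...) {
  cat(sprintf("<cessalex_profile> lexicon %s (K=%d), field %s, %d forum(s)\n",
              attr(x, "lex_name"), length(attr(x, "categories")),
              attr(x, "field"), length(unique(x$forum))))
  NextMethod()
}

#' Per-forum lexicon match totals (emotion scores)
#'
#' The emotion score of a forum corpus is its total count of emotion word
#' bank matches, used by the median-split density filter. Optionally also
#' reports the per-token match rate.
#'
#' @inheritParams corpus_profile
#' @param rate Also compute `rate` = total matches / total tokens.
#' @return A tibble with columns `forum`, `score` (and `rate`).
#' @export
emotion_scores <- function(posts, lex, field = c("body", "title_body"),
                           rate = FALSE) {
  stopifnot(inherits(lex, "cessalex_lexicon"))
  field <- match.arg(field)
  toks <- tokens_by_forum(posts, field)
  out <- tibble(
    forum = names(toks),
    score = vapply(toks, function(tk) attr(count_matches(tk, lex), "total"),
                   numeric(1))
  )
  if (rate) out$rate <- out$score / pmax(1, lengths(toks))
  out
}

#' Median-split retention of emotion-rich forums
#'
#' Excludes "emotion-poor" forums: only forums whose score is strictly
#' greater than the sample median of all supplied scores are retained.
#' With n distinct scores this keeps floor(n/2) forums (54 of 108,
#' 47 of 95).
#'
#' @param scores A tibble with columns `forum` and `score` (e.g. from
#'   [emotion_scores()]), or a named numeric vector.
#' @return The retained rows of `scores`, as a tibble.
#' @export
median_split_retain <- function(scores) {
  if (is.numeric(scores) && !is.null(names(scores))) {
    scores <- tibble(forum = names(scores), score = unname(scores))
  }
  if (!all(c("forum", "score") %in% names(scores))) {
    abort("`scores` must have columns `forum` and `score`.")
  }
  if (nrow(scores) < 2L) abort("median split needs at least 2 forums")
  med <- median(scores$score)
  out <- dplyr::filter(as_tibble(scores), .data$score > med)
  if (nrow(out) == 0L) {
    warn("median split retained no forums (scores all at or below the median)")
  }
  out
}

#' Flag percentile outlier categories against a control sample
#'
#' A target forum is an outlier on a category when its occurrence frequency
#' exceeds the q-th percentile of the control forums' frequencies on that
#' category. Percentiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7 by default).
#'
#' @param target A [corpus_profile()] of one or more target forums.
#' @param controls A [corpus_profile()] of the control forums.
#' @param q Percentile (0-100). Default 95.
#' @param type Quantile interpolation type passed to [stats::quantile()].
#' @return A tibble with columns `forum`, `category`, `frequency`,
#'   `threshold`, `is_outlier`.
#' @export
percentile_outliers <- function(target, controls, q = 95, type = 7) {
  for (p in list(target, controls)) {
    if (!inherits(p, "cessalex_profile")) {
      abort("`target` and `controls` must be cessalex_profile objects")
    }
  }
  if (!identical(attr(target, "lex_name"), attr(controls, "lex_name")) ||
      !identical(attr(target, "categories"), attr(controls, "categories"))) {
    abort("target and control profiles use different lexicons")
  }
  n_ctrl <- length(unique(controls$forum))
  if (n_ctrl < 20L) {
    warn(sprintf("only %d control profiles; percentile thresholds will be coarse",
                 n_ctrl))
  }
  thr <- controls |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(threshold = quantile(.data$frequency, q / 100,
                                          type = type, names = FALSE),
                     .groups = "drop")
  target |>
    as_tibble() |>
    dplyr::select("forum", "category", "frequency") |>
    dplyr::left_join(thr, by = "category") |>
    dplyr::mutate(is_outlier = .data$frequency > .data$threshold)
}
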