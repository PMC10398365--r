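#' Log-spaced abstinence-duration bins
#'
#' Builds the binning used for abstinence trajectories: a day-0 bin
#' `[0, 1)` capturing posts made within the first 24 hours, then
#' `n_short - 1` logarithmically spaced bins from day 1 to `split_day`,
#' then `n_long` logarithmically spaced bins from `split_day` to `cutoff`.
#' With the defaults this gives 15 bins: 9 short-term bins below 100 days
#' and 6 long-term bins from 100 to 1000 days, with 100 itself an edge so
#' day 99.9 is short-term and day 100 long-term. The final bin is closed
#' at `cutoff`.
#'
#' @param cutoff Maximum day included. Default 1000.
#' @param split_day Boundary between short- and long-term bins.
#'   Default 100.
#' @param n_short,n_long Number of short/long bins. Defaults 9 and 6.
#' @return A tibble of class `cessalex_bins` with columns `bin`, `lower`,
#'   `upper`, `level` (`"short"`/`"long"`) and attribute `edges` (length
#'   `n_short + n_long + 1`).
#' @export
abstinence_bins <- function(cutoff = 1000, split_day = 100,
                            n_short = 9, n_long = 6) {
  stopifnot(cutoff > split_day, split_day > 1, n_short >= 2, n_long >= 1)
  short_edges <- c(0, 10^seq(0, log10(split_day), length.out = n_short))
  long_edges <- 10^seq(log10(split_day), log10(cutoff),
                       length.out = n_long + 1)[-1]
  edges <- c(short_edges, long_edges)
  out <- tibble(
    bin = seq_len(n_short + n_long),
    lower = edges[-length(edges)],
    upper = edges[-1],
    level = rep(c("short", "long"), c(n_short, n_long))
  )
  structure(out, edges = edges,
            class = c("cessalex_bins", class(out)))
}

#' Extract the abstinence-tagged analysis set
#'
#' Keeps textual posts carrying a self-reported abstinence duration and
#' truncates to the `n_keep` most recent, so that forums with different
#' tagging volumes contribute the same number of posts.
#'
#' @param posts A posts tibble.
#' @param n_keep Posts to retain per forum. Default 1205.
#' @return A tibble of tagged text posts. If fewer than `n_keep` qualify a
#'   warning is raised and all qualifying posts are returned.
#' @export
filter_abstinence_tagged <- function(posts, n_keep = 1205) {
  tagged <- posts |>
    filter_text_posts() |>
    dplyr::filter(!is.na(.data$abstinence_days))
  if (nrow(tagged) == 0L) {
    warn("no abstinence-tagged text posts found")
    return(tagged)
  }
  if (nrow(tagged) < n_keep) {
    warn(sprintf("only %d abstinence-tagged posts (requested %d); returning all",
                 nrow(tagged), n_keep))
    return(tagged)
  }
  truncate_recent(tagged, n_keep)
}

#' Share of posts made within the first 24 hours of abstinence
#'
#' @param posts Abstinence-tagged posts.
#' @return Percentage of posts with `abstinence_days < 1`.
#' @export
first_day_fraction <- function(posts) {
  if (nrow(posts) == 0L) abort("no posts supplied")
  days <- posts$abstinence_days
  if (anyNA(days)) abort("posts must all carry abstinence_days")
  100 * mean(days < 1)
}

#' Chance expectation for first-day posting under a uniform model
#'
#' If users were equally likely to post at any abstinence duration over a
#' range of `range_days` days, the expected share of posts in the first
#' 24 hours would be `100 / range_days` percent (0.01% for the default
#' 10,000-day range).
#'
#' @param range_days Span of possible abstinence durations in days.
#' @return Percentage expected in the first day.
#' @export
uniform_chance_first_day <- function(range_days = 10000) {
  if (!is.numeric(range_days) || range_days < 1) {
    abort("range_days must be at least 1")
  }
  100 / range_days
}

#' Emotion profile of first-day posts
#'
#' Pools all posts made within the first 24 hours of abstinence and
#' profiles them against a lexicon; reports the `top_m` categories by
#' occurrence frequency (ties broken lexicographically).
#'
#' @param posts Abstinence-tagged posts.
#' @param lex A [lexicon()].
#' @param top_m Number of leading categories to report. Default 5.
#' @inheritParams corpus_profile
#' @return A [corpus_profile()] of the pooled day-0 posts (forum label
#'   `"first24h"`), with attribute `top_categories`.
#' @export
first_day_profile <- function(posts, lex, top_m = 5,
                              field = c("body", "title_body")) {
  field <- match.arg(field)
  day0 <- dplyr::filter(posts, .data$abstinence_days < 1)
  if (nrow(day0) == 0L) abort("no posts within the first 24 hours of abstinence")
  day0$forum <- "first24h"
  prof <- corpus_profile(day0, lex, field = field)
  ord <- order(-prof$frequency, prof$category)
  attr(prof, "top_categories") <- prof$category[ord][seq_len(min(top_m, nrow(prof)))]
  prof
}

#' Bin abstinence-tagged posts and profile emotions per bin
#'
#' Posts beyond the bin cutoff are excluded; each remaining post is
#' assigned to the half-open interval `[lower, upper)` containing its day
#' value (the final bin is closed at the cutoff). Lexicon counts are pooled
#' within each bin and normalised per bin, so every non-empty bin's
#' percentages sum to 100.
#'
#' @param posts Abstinence-tagged posts (one forum's analysis set).
#' @param lex A [lexicon()].
#' @param bins An [abstinence_bins()] table.
#' @inheritParams corpus_profile
#' @return A tibble of class `cessalex_binned` with columns `bin`, `level`,
#'   `category`, `count`, `frequency`, and attributes `n_posts` (posts per
#'   bin), `bin_matches` (lexicon matches per bin), `bins`, `lex_name`,
#'   `categories`.
#' @export
bin_posts <- function(posts, lex, bins = abstinence_bins(),
                      field = c("body", "title_body")) {
  stopifnot(inherits(bins, "cessalex_bins"), inherits(lex, "cessalex_lexicon"))
  field <- match.arg(field)
  edges <- attr(bins, "edges")
  days <- posts$abstinence_days
  if (anyNA(days)) abort("posts must all carry abstinence_days")
  keep <- days >= edges[1] & days <= edges[length(edges)]
  posts <- posts[keep, , drop = FALSE]
  idx <- findInterval(posts$abstinence_days, edges, rightmost.closed = TRUE)

  cats <- lexicon_categories(lex)
  text <- if (field == "body") posts$body else paste(posts$title, posts$body)
  toks <- preprocess_text(text, collapse = FALSE)
  rows <- lapply(bins$bin, function(b) {
    tk <- unlist(toks[idx == b], use.names = FALSE)
    cm <- count_matches(tk, lex)
    total <- attr(cm, "total")
    tibble(bin = b, level = bins$level[b], category = cm$category,
           count = cm$count,
           frequency = if (total > 0) 100 * cm$count / total else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  structure(
    out,
    n_posts = tabulate(idx, nbins = nrow(bins)),
    bin_matches = vapply(split(out$count, out$bin), sum, numeric(1),
                         USE.NAMES = FALSE),
    bins = bins,
    lex_name = attr(lex, "lex_name"),
    categories = cats,
    field = field,
    class = c("cessalex_binned", class(out))
  )
}

#' Two-way emotion-by-abstinence ANOVA on a binned emotion table
#'
#' Fits a fixed-effects two-way ANOVA with interaction on the per-bin
#' occurrence percentages: factors are emotion category (K levels) and
#' abstinence level (short/long), with bins serving as replicates within
#' abstinence level. Sums of squares are sequential (type I) with emotion
#' entered first; because every bin's percentages sum to 100, the
#' abstinence main effect is analytically zero for any per-bin-normalised
#' table, and the sequential/partial distinction is immaterial for that
#' term.
#'
#' @param binned A [bin_posts()] table.
#' @return An object of class `cessalex_anova` wrapping the [stats::aov()]
#'   fit; see [tidy.cessalex_anova()] and [glance.cessalex_anova()].
#' @export
two_way_anova <- function(binned) {
  stopifnot(inherits(binned, "cessalex_binned"))
  empty <- which(attr(binned, "bin_matches") == 0)
  if (length(empty) > 0L) {
    abort(paste0("bin(s) with no lexicon matches: ",
                 paste(empty, collapse = ", ")))
  }
  cats <- attr(binned, "categories")
  df <- tibble(
    frequency = binned$frequency,
    emotion = factor(binned$category, levels = cats),
    abstinence = factor(binned$level, levels = c("short", "long"))
  )
  fit <- aov(frequency ~ emotion * abstinence, data = df)
  structure(list(fit = fit, data = df, K = length(cats)),
            class = "cessalex_anova")
}

#' @export
print.cessalex_anova <- function(x, ...) {
  cat("<cessalex_anova> two-way emotion x abstinence ANOVA\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy the two-way ANOVA
#'
#' @param x A `cessalex_anova`.
#' @param ... Unused.
#' @return `tidy()` returns one row per term (`emotion`, `abstinence`,
#'   `emotion:abstinence`, `Residuals`) with `df`, `sumsq`, `meansq`,
#'   `statistic` and `p.value`; `glance()` returns a one-row summary with
#'   the three effect F statistics, their df and p-values.
#' @method tidy cessalex_anova
#' @export
tidy.cessalex_anova <- function(x, ...) {
  s <- summary(x$fit)[[1]]
  tibble(
    term = trimws(rownames(s)),
    df = s$Df,
    sumsq = s$`Sum Sq`,
    meansq = s$`Mean Sq`,
    statistic = s$`F value`,
    p.value = s$`Pr(>F)`
  )
}

#' @rdname tidy.cessalex_anova
#' @method glance cessalex_anova
#' @export
glance.cessalex_anova <- function(x, ...) {
  td <- tidy(x)
  eff <- function(term, col) td[[col]][td$term == term]
  tibble(
    df_emotion = eff("emotion", "df"),
    df_abstinence = eff("abstinence", "df"),
    df_interaction = eff("emotion:abstinence", "df"),
    df_residual = eff("Residuals", "df"),
    f_emotion = eff("emotion", "statistic"),
    f_abstinence = eff("abstinence", "statistic"),
    f_interaction = eff("emotion:abstinence", "statistic"),
    p_emotion = eff("emotion", "p.value"),
    p_abstinence = eff("abstinence", "p.value"),
    p_interaction = eff("emotion:abstinence", "p.value")
  )
}

#' Post-hoc short- vs long-term abstinence contrasts
#'
#' Two-sided independent-samples t tests comparing an emotion's per-bin
#' percentage across short-term bins versus long-term bins, restricted to
#' a preselected emotion subset to limit multiple comparisons, with a
#' Bonferroni threshold of `alpha / length(emotions)`. Pooled-variance t
#' (df = n1 + n2 - 2) is the default; set `var_equal = FALSE` for Welch.
#'
#' @param binned A [bin_posts()] table.
#' @param emotions Character vector of categories to test (e.g. the
#'   outlier emotions from the profiling stage).
#' @param alpha Familywise alpha. Default 0.05.
#' @param var_equal Pooled-variance t if `TRUE` (default), Welch otherwise.
#' @return A tibble with one row per emotion: `estimate` (short mean minus
#'   long mean), `statistic`, `df`, `p.value`, `alpha_bonferroni`,
#'   `significant`.
#' @export
posthoc_ttests <- function(binned, emotions, alpha = 0.05, var_equal = TRUE) {
  stopifnot(inherits(binned, "cessalex_binned"))
  cats <- attr(binned, "categories")
  bad <- setdiff(emotions, cats)
  if (length(bad) > 0L) {
    abort(paste0("emotions not in lexicon: ", paste(bad, collapse = ", ")))
  }
  thr <- alpha / length(emotions)
  rows <- lapply(emotions, function(em) {
    x <- binned$frequency[binned$category == em & binned$level == "short"]
    y <- binned$frequency[binned$category == em & binned$level == "long"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      abort(paste0("need >= 2 non-empty bins per level for emotion ", em))
    }
    res <- tryCatch(
      t.test(x, y, var.equal = var_equal),
      error = function(e) NULL # constant data in both groups
    )
    if (is.null(res)) {
      tibble(emotion = em, estimate = mean(x) - mean(y), statistic = 0,
             df = if (var_equal) length(x) + length(y) - 2 else NA_real_,
             p.value = 1)
    } else {
      tibble(emotion = em, estimate = unname(diff(rev(res$estimate))),
             statistic = unname(res$statistic),
             df = unname(res$parameter), p.value = res$p.value)
    }
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(alpha_bonferroni = thr,
                  significant = .data$p.value < thr)
}
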