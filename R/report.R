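default_config <- function() {
  list(
    posts = NULL,
    lexicon = "emotion",
    field = "body",
    targets = character(0),
    min_text = 3000,
    window = NULL,
    truncate_n = NULL,
    q = 95,
    top_k = 5,
    abstinence = NULL
  )
}

resolve_lexicon <- function(lexicon) {
  if (inherits(lexicon, "cessalex_lexicon")) return(lexicon)
  if (identical(lexicon, "emotion")) return(default_emotion_lexicon())
  if (identical(lexicon, "time")) return(default_time_lexicon())
  read_lexicon(lexicon)
}

#' Run the full profiling pipeline
#'
#' Executes ingest, the text-density inclusion filter, text-post
#' filtering, truncation to a common corpus size, the median-split density
#' filter, per-forum profiling, percentile outlier detection for the
#' target forums, the cosine-similarity matrix with top-k neighbours, and
#' (optionally) the abstinence-duration analyses. Every filter logs the
#' number of units before and after. The run is fully deterministic:
#' identical inputs and config give an identical report.
#'
#' @param config A list (or path to a YAML/JSON file) with elements:
#'   `posts` (JSONL path or posts tibble), `lexicon` (`"emotion"`,
#'   `"time"`, a file path, or a [lexicon()]), `field`, `targets`
#'   (character vector of target forums), `min_text`, `window` (set to
#'   the extraction window, e.g. 5025, to apply the inclusion filter, or
#'   `NULL` to skip it), `truncate_n` (e.g. 3003, or `NULL`), `q`,
#'   `top_k`, and optional `abstinence` = list(`forums`, `n_keep`,
#'   `emotions`, `alpha`, plus any [abstinence_bins()] arguments).
#' @return A list of class `cessalex_report` with elements `config`,
#'   `lexicon_hash`, `log`, `scores`, `retained`, `profiles`, `outliers`,
#'   `simmat`, `top_k`, `abstinence`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config)
  lex <- resolve_lexicon(cfg$lexicon)

  posts <- cfg$posts
  if (is.character(posts)) posts <- read_posts_jsonl(posts)
  if (is.null(posts) || nrow(posts) == 0L) abort("pipeline stage ingest: no posts")

  log <- list()
  note <- function(stage, n_before, n_after, rule) {
    log[[length(log) + 1L]] <<- tibble(stage = stage, n_before = n_before,
                                       n_after = n_after, rule = rule)
  }

  by_forum <- split(as_tibble(posts), posts$forum)
  note("ingest", nrow(posts), nrow(posts),
       sprintf("%d forums read", length(by_forum)))

  if (!is.null(cfg$window)) {
    ok <- vapply(by_forum, passes_inclusion, logical(1),
                 min_text = cfg$min_text, window = cfg$window)
    note("inclusion", length(by_forum), sum(ok),
         sprintf(">= %d text posts of %d-post window", cfg$min_text,
                 cfg$window))
    by_forum <- by_forum[ok]
  }

  n_before <- sum(vapply(by_forum, nrow, integer(1)))
  by_forum <- lapply(by_forum, filter_text_posts)
  note("text_filter", n_before, sum(vapply(by_forum, nrow, integer(1))),
       "body yields >= 1 token")

  if (!is.null(cfg$truncate_n)) {
    n_before <- sum(vapply(by_forum, nrow, integer(1)))
    by_forum <- lapply(by_forum, truncate_recent, n = cfg$truncate_n)
    note("truncate", n_before, sum(vapply(by_forum, nrow, integer(1))),
         sprintf("most recent %d text posts", cfg$truncate_n))
  }

  corpus <- dplyr::bind_rows(by_forum)
  scores <- emotion_scores(corpus, lex, field = cfg$field)
  retained <- median_split_retain(scores)
  note("median_split", nrow(scores), nrow(retained),
       "emotion score strictly above sample median")
  if (nrow(retained) == 0L) {
    abort("pipeline stage median_split: no forums retained")
  }

  kept <- dplyr::filter(corpus, .data$forum %in% retained$forum)
  profiles <- corpus_profile(kept, lex, field = cfg$field)

  targets <- intersect(cfg$targets, retained$forum)
  outliers <- NULL
  if (length(targets) > 0L) {
    ctrl_forums <- setdiff(retained$forum, targets)
    split_prof <- function(forums) {
      new_profile(dplyr::filter(as_tibble(profiles), .data$forum %in% forums),
                  lex, cfg$field, attr(profiles, "totals")[forums])
    }
    outliers <- percentile_outliers(split_prof(targets),
                                    split_prof(ctrl_forums), q = cfg$q)
  }

  simmat <- NULL
  top_k <- NULL
  if (nrow(retained) >= 2L) {
    simmat <- similarity_matrix(profiles)
    if (length(targets) > 0L && cfg$top_k < nrow(retained)) {
      top_k <- dplyr::bind_rows(lapply(targets, function(tg) {
        dplyr::mutate(top_k_similar(simmat, tg, k = cfg$top_k),
                      target = tg, .before = 1)
      }))
    }
  }

  abst <- NULL
  if (!is.null(cfg$abstinence)) {
    ab <- utils::modifyList(
      list(forums = character(0), n_keep = 1205, cutoff = 1000,
           emotions = c("anxiety", "disgust", "pride", "gratitude"),
           alpha = 0.05, top_m = 5),
      cfg$abstinence)
    bins <- abstinence_bins(cutoff = ab$cutoff)
    abst <- lapply(setNames(ab$forums, ab$forums), function(fr) {
      ps <- dplyr::filter(as_tibble(posts), .data$forum == fr)
      tagged <- filter_abstinence_tagged(ps, n_keep = ab$n_keep)
      if (nrow(tagged) == 0L) return(NULL)
      binned <- bin_posts(tagged, lex, bins = bins, field = cfg$field)
      fd_prof <- tryCatch(
        first_day_profile(tagged, lex, top_m = ab$top_m, field = cfg$field),
        error = function(e) NULL)
      list(
        n_tagged = nrow(tagged),
        first_day_pct = first_day_fraction(tagged),
        chance_pct = uniform_chance_first_day(),
        first_day_top = if (!is.null(fd_prof)) attr(fd_prof, "top_categories"),
        first_day_profile = fd_prof,
        binned = binned,
        anova = glance(two_way_anova(binned)),
        ttests = posthoc_ttests(binned, ab$emotions, alpha = ab$alpha)
      )
    })
    note("abstinence", length(ab$forums), sum(!vapply(abst, is.null, TRUE)),
         sprintf("tagged text posts, most recent %d, cutoff %d days",
                 ab$n_keep, ab$cutoff))
  }

  structure(
    list(
      config = cfg,
      lexicon_hash = rlang::hash(as.data.frame(lex[c("category", "word")])),
      lex_name = attr(lex, "lex_name"),
      log = dplyr::bind_rows(log),
      scores = scores,
      retained = retained,
      profiles = profiles,
      outliers = outliers,
      simmat = simmat,
      top_k = top_k,
      abstinence = abst
    ),
    class = "cessalex_report")
}

#' @export
print.cessalex_report <- function(x, ...) {
  cat(sprintf("<cessalex_report> lexicon %s, %d forums retained of %d\n",
              x$lex_name, nrow(x$retained), nrow(x$scores)))
  print(x$log)
  invisible(x)
}

#' Compare two pipeline runs (replication analysis)
#'
#' Compares a discovery run with a replication run on the same lexicon:
#' for every target forum present in both reports it computes the overlap
#' and Jaccard index of flagged outlier categories, the Jaccard index of
#' the top-k neighbour sets, and per-category frequency deltas.
#'
#' @param a,b `cessalex_report` objects from [run_pipeline()].
#' @return A list of class `cessalex_comparison` with elements `targets`
#'   (one row per target forum) and `frequency_deltas`.
#' @export
compare_runs <- function(a, b) {
  stopifnot(inherits(a, "cessalex_report"), inherits(b, "cessalex_report"))
  if (!identical(a$lexicon_hash, b$lexicon_hash)) {
    abort("runs used different lexicons; comparison undefined")
  }
  jaccard <- function(x, y) {
    if (length(x) == 0L && length(y) == 0L) return(1)
    length(intersect(x, y)) / length(union(x, y))
  }
  out_set <- function(rep, fr) {
    if (is.null(rep$outliers)) return(character(0))
    o <- dplyr::filter(rep$outliers, .data$forum == fr, .data$is_outlier)
    o$category
  }
  nb_set <- function(rep, fr) {
    if (is.null(rep$top_k)) return(character(0))
    rep$top_k$forum[rep$top_k$target == fr]
  }
  targets <- intersect(unique(a$outliers$forum %||% character(0)),
                       unique(b$outliers$forum %||% character(0)))
  rows <- lapply(targets, function(fr) {
    oa <- out_set(a, fr); ob <- out_set(b, fr)
    tibble(forum = fr,
           n_outliers_a = length(oa), n_outliers_b = length(ob),
           n_outlier_overlap = length(intersect(oa, ob)),
           jaccard_outliers = jaccard(oa, ob),
           jaccard_top_k = jaccard(nb_set(a, fr), nb_set(b, fr)))
  })
  deltas <- dplyr::inner_join(
    dplyr::select(as_tibble(a$profiles), "forum", "category",
                  freq_a = "frequency"),
    dplyr::select(as_tibble(b$profiles), "forum", "category",
                  freq_b = "frequency"),
    by = c("forum", "category")) |>
    dplyr::mutate(delta = .data$freq_a - .data$freq_b)
  structure(list(targets = dplyr::bind_rows(rows), frequency_deltas = deltas),
            class = "cessalex_comparison")
}

#' @export
print.cessalex_comparison <- function(x, ...) {
  cat("<cessalex_comparison>\n")
  print(x$targets)
  invisible(x)
}

#' Write a pipeline report to CSV files
#'
#' Emits the report's result surfaces as plain CSV: scores, retained
#' forums, profiles, outlier flags, the similarity matrix, top-k
#' neighbours, the filter log, and per-forum abstinence results.
#'
#' @param report A `cessalex_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cessalex_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  put <- function(df, name) {
    write.csv(as.data.frame(df), file.path(dir, name), row.names = FALSE)
  }
  put(report$log, "log.csv")
  put(report$scores, "scores.csv")
  put(report$retained, "retained.csv")
  put(report$profiles, "profiles.csv")
  if (!is.null(report$outliers)) put(report$outliers, "outliers.csv")
  if (!is.null(report$simmat)) {
    write.csv(as.data.frame(unclass(report$simmat)),
              file.path(dir, "similarity.csv"))
  }
  if (!is.null(report$top_k)) put(report$top_k, "top_k.csv")
  for (fr in names(report$abstinence %||% list())) {
    res <- report$abstinence[[fr]]
    if (is.null(res)) next
    put(res$binned, paste0("abstinence_binned_", fr, ".csv"))
    put(res$anova, paste0("abstinence_anova_", fr, ".csv"))
    put(res$ttests, paste0("abstinence_ttests_", fr, ".csv"))
  }
  invisible(dir)
}
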