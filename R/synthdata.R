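with_preserved_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Reserved-prefix filler vocabulary
#'
#' Non-lexicon filler words used by the corpus generator. The reserved
#' prefix guarantees the filler can never collide with a lexicon word, so
#' recounting generated text reproduces the ground-truth category counts
#' exactly.
#'
#' @param n Vocabulary size.
#' @param prefix Reserved prefix. Default `"zq"`.
#' @return Character vector of `n` distinct filler words.
#' @export
filler_vocabulary <- function(n = 400, prefix = "zq") {
  paste0(prefix, "w", seq_len(n))
}

#' Specify a synthetic forum
#'
#' Describes one forum for [generate_corpus()]: its size, its true emotion
#' composition over the lexicon categories, how emotion-dense its text is,
#' post length, the fraction of image-only (empty-body) posts, and an
#' optional abstinence model. The abstinence model places a point mass of
#' posting probability in the first 24 hours and draws the remaining
#' durations log-uniformly out to `max_day`; posts beyond 100 days can
#' shift the emotion composition (`post100_shift`, a named additive change
#' renormalised onto the simplex), emulating e.g. an anxiety decrease with
#' sustained abstinence.
#'
#' @param forum Forum name.
#' @param n_posts Number of posts.
#' @param emotion_probs Named probability vector over lexicon categories
#'   (a K-simplex; names must match the lexicon).
#' @param emotion_rate Fraction of tokens drawn from the lexicon.
#' @param post_length_mean,post_length_size Mean and dispersion (negative
#'   binomial `mu`/`size`) of the token count of a non-image post.
#' @param image_only_frac Fraction of empty-body posts.
#' @param n_authors Size of the author pool.
#' @param abstinence `NULL`, or a list with elements `day0_mass`
#'   (probability a post is made within the first 24 hours; default 0.07),
#'   `max_day` (log-uniform tail limit; default 10000) and `post100_shift`
#'   (named numeric, default `c(anxiety = -0.08, gratitude = 0.04)`).
#' @return A list of class `cessalex_forum_spec`.
#' @export
forum_spec <- function(forum, n_posts = 3003, emotion_probs,
                       emotion_rate = 0.08, post_length_mean = 60,
                       post_length_size = 5, image_only_frac = 0,
                       n_authors = 2400, abstinence = NULL) {
  if (is.null(names(emotion_probs)) || any(!nzchar(names(emotion_probs)))) {
    abort("emotion_probs must be a named vector over lexicon categories")
  }
  if (any(emotion_probs < 0) || abs(sum(emotion_probs) - 1) > 1e-8) {
    abort("emotion_probs must be a probability simplex (nonnegative, sum 1)")
  }
  stopifnot(image_only_frac >= 0, image_only_frac <= 1,
            emotion_rate >= 0, emotion_rate <= 1, n_posts >= 1)
  if (!is.null(abstinence)) {
    abstinence <- utils::modifyList(
      list(day0_mass = 0.07, max_day = 10000,
           post100_shift = c(anxiety = -0.08, gratitude = 0.04)),
      abstinence)
    stopifnot(abstinence$day0_mass >= 0, abstinence$day0_mass <= 1,
              abstinence$max_day >= 1)
  }
  structure(
    list(forum = forum, n_posts = as.integer(n_posts),
         emotion_probs = emotion_probs, emotion_rate = emotion_rate,
         post_length_mean = post_length_mean,
         post_length_size = post_length_size,
         image_only_frac = image_only_frac, n_authors = n_authors,
         abstinence = abstinence),
    class = "cessalex_forum_spec")
}

# Apply a named additive shift to a simplex and renormalise; shift names
# absent from the simplex are ignored.
shift_probs <- function(p, shift) {
  shift <- shift[names(shift) %in% names(p)]
  p2 <- p
  p2[names(shift)] <- pmax(0, p2[names(shift)] + shift)
  p2 / sum(p2)
}

# Wrap a fraction of tokens in punctuation/markup noise that the
# preprocessor removes without creating or destroying tokens.
inject_noise <- function(tokens, frac = 0.25) {
  n <- length(tokens)
  pick <- which(runif(n) < frac)
  if (length(pick) == 0L) return(tokens)
  style <- sample.int(4L, length(pick), replace = TRUE)
  tk <- tokens[pick]
  tk[style == 1L] <- paste0("(", tk[style == 1L], ")")
  tk[style == 2L] <- paste0(tk[style == 2L], "!!")
  tk[style == 3L] <- paste0("<b>", tk[style == 3L], "</b>")
  tk[style == 4L] <- toupper(tk[style == 4L])
  tokens[pick] <- tk
  tokens
}

#' Generate a synthetic forum corpus with ground truth
#'
#' Draws `n_posts` posts according to a [forum_spec()]: token counts follow
#' a negative binomial law, each token is a lexicon word with probability
#' `emotion_rate` (category drawn from `emotion_probs`, word uniform within
#' the category) and a reserved-prefix filler word otherwise; a fraction of
#' tokens is wrapped in punctuation, markup and case noise; image-only
#' posts get empty bodies. Abstinence-enabled specs attach
#' `abstinence_days` (point mass below day 1, log-uniform tail) and apply
#' the spec's `post100_shift` to category draws for posts beyond 100 days.
#' Output is deterministic given the seed, and recounting the generated
#' text through [preprocess_text()] and [count_matches()] reproduces the
#' truth counts exactly (provided the lexicon's categories share no words).
#'
#' @param spec A [forum_spec()].
#' @param lex A [lexicon()] whose categories match
#'   `names(spec$emotion_probs)`.
#' @param seed Integer seed for this corpus.
#' @param base_time Timestamp (seconds) of the newest post.
#' @return A list with elements `posts` (tibble, newest first) and `truth`
#'   (list: `spec`, `counts` tibble of realised category counts, and for
#'   abstinence-enabled specs `counts_short`/`counts_long` split at 100
#'   days).
#' @export
generate_corpus <- function(spec, lex, seed = 1,
                            base_time = 1606780800) {
  stopifnot(inherits(spec, "cessalex_forum_spec"),
            inherits(lex, "cessalex_lexicon"))
  cats <- lexicon_categories(lex)
  if (!setequal(names(spec$emotion_probs), cats)) {
    abort("emotion_probs names do not match lexicon categories")
  }
  p <- spec$emotion_probs[cats]
  words_by_cat <- split(lex$word, factor(lex$category, levels = cats))
  filler <- filler_vocabulary()
  if (any(lex$word %in% filler)) abort("lexicon collides with filler vocabulary")

  with_preserved_seed(seed, {
    n <- spec$n_posts
    image <- runif(n) < spec$image_only_frac

    days <- rep(NA_real_, n)
    shifted <- rep(FALSE, n)
    if (!is.null(spec$abstinence)) {
      ab <- spec$abstinence
      day0 <- runif(n) < ab$day0_mass
      days <- ifelse(day0, runif(n, 0, 1), 10^runif(n, 0, log10(ab$max_day)))
      shifted <- days > 100
    }

    len <- rnbinom(n, size = spec$post_length_size,
                   mu = spec$post_length_mean) + 1L
    len[image] <- 0L
    total <- sum(len)
    post_of <- rep.int(seq_len(n), len)
    is_emo <- runif(total) < spec$emotion_rate

    cat_idx <- integer(total)
    for (grp in list(which(is_emo & !shifted[post_of]),
                     which(is_emo & shifted[post_of]))) {
      if (length(grp) == 0L) next
      pr <- if (any(shifted[post_of[grp]])) {
        shift_probs(p, spec$abstinence$post100_shift)
      } else p
      cat_idx[grp] <- sample.int(length(cats), length(grp),
                                 replace = TRUE, prob = pr)
    }

    tokens <- character(total)
    tokens[!is_emo] <- filler[sample.int(length(filler), sum(!is_emo),
                                         replace = TRUE)]
    for (ci in unique(cat_idx[is_emo])) {
      at <- which(is_emo & cat_idx == ci)
      w <- words_by_cat[[ci]]
      tokens[at] <- w[sample.int(length(w), length(at), replace = TRUE)]
    }

    truth_counts <- tibble(
      category = cats,
      count = tabulate(cat_idx[is_emo], nbins = length(cats))
    )
    truth <- list(spec = spec, counts = truth_counts)
    if (!is.null(spec$abstinence)) {
      tok_shift <- shifted[post_of]
      truth$counts_short <- tibble(
        category = cats,
        count = tabulate(cat_idx[is_emo & !tok_shift], nbins = length(cats)))
      truth$counts_long <- tibble(
        category = cats,
        count = tabulate(cat_idx[is_emo & tok_shift], nbins = length(cats)))
    }

    noisy <- inject_noise(tokens)
    bodies <- character(n)
    if (total > 0L) {
      grouped <- split(noisy, factor(post_of, levels = seq_len(n)))
      bodies <- vapply(grouped, paste, character(1), collapse = " ")
    }
    bodies[image] <- ""

    posts <- tibble(
      forum = spec$forum,
      author = paste0("user", sample.int(spec$n_authors, n, replace = TRUE)),
      created_utc = base_time - 60 * (seq_len(n) - 1),
      title = vapply(seq_len(n), function(i) {
        paste(filler[sample.int(length(filler), 3L)], collapse = " ")
      }, character(1)),
      body = unname(bodies),
      abstinence_days = days
    )
    list(posts = posts, truth = truth)
  })
}

# Marginal category composition of a spec, averaging over the abstinence
# day distribution: posts beyond day 100 draw from the shifted simplex,
# and their expected share is (1 - day0_mass) * (1 - 2 / log10(max_day))
# under the log-uniform tail.
marginal_probs <- function(spec) {
  p <- spec$emotion_probs
  if (is.null(spec$abstinence)) return(p)
  ab <- spec$abstinence
  w <- (1 - ab$day0_mass) * max(0, 1 - 2 / log10(ab$max_day))
  (1 - w) * p + w * shift_probs(p, ab$post100_shift)
}

# Fill a simplex: fixed named probabilities, remainder spread evenly.
compose_probs <- function(cats, elevated = numeric(0)) {
  p <- setNames(rep(0, length(cats)), cats)
  p[names(elevated)] <- elevated
  rest <- setdiff(cats, names(elevated))
  p[rest] <- (1 - sum(elevated)) / length(rest)
  p
}

#' Generate a full synthetic study bundle
#'
#' Stands in for the extraction of a discovery (or replication) data set:
#' `n_control` control forums whose emotion compositions are drawn from a
#' Dirichlet prior centred on the uniform composition, plus `n_target`
#' cessation-style target forums with elevated compositions for selected
#' categories (anxiety high in all, plus per-forum outlier emotions:
#' pride/gratitude, disgust, and disgust/anxiety), mirroring the structure
#' the profiling pipeline expects. The first two targets carry abstinence
#' metadata with the default first-day point mass and post-100-day shift.
#'
#' Target categories whose true probability exceeds the 99th percentile of
#' the control Dirichlet marginal are recorded as `expected_outliers` so
#' recovery can be checked against construction.
#'
#' @param n_control Number of control forums. Default 105.
#' @param n_target Number of target forums (up to 3 presets). Default 3.
#' @param seed Integer seed for the whole bundle; per-forum substreams are
#'   derived deterministically.
#' @param lex A [lexicon()]. Default [default_emotion_lexicon()].
#' @param n_posts Posts per forum. Default 3003.
#' @param post_length_mean Mean tokens per post. Default 12 (reduced
#'   length for desk-scale studies).
#' @param concentration Dirichlet concentration of the control prior.
#'   Default 150.
#' @param write_dir If non-NULL, write `posts.jsonl` and `truth.csv` there.
#' @return A list with `posts` (all forums), `specs`, `truth` (forum x
#'   category tibble of true probabilities and realised counts),
#'   `expected_outliers` (named list per target), `control_forums`,
#'   `target_forums`.
#' @export
generate_study <- function(n_control = 105, n_target = 3, seed = 1,
                           lex = default_emotion_lexicon(),
                           n_posts = 3003, post_length_mean = 12,
                           concentration = 150, write_dir = NULL) {
  stopifnot(n_control >= 2, n_target >= 0, n_target <= 3)
  cats <- lexicon_categories(lex)
  K <- length(cats)

  target_defs <- list(
    cess_alcohol = list(
      elevated = c(anxiety = 0.16, pride = 0.10, gratitude = 0.10,
                   sadness = 0.09, optimism = 0.09, joy = 0.08, love = 0.08),
      abstinence = list()),
    cess_nicotine = list(
      elevated = c(anxiety = 0.16, disgust = 0.12, gratitude = 0.07,
                   sadness = 0.09, optimism = 0.09, joy = 0.08, love = 0.08),
      abstinence = list()),
    cess_cannabis = list(
      elevated = c(anxiety = 0.17, disgust = 0.11,
                   sadness = 0.09, optimism = 0.09, joy = 0.08, love = 0.08),
      abstinence = NULL)
  )[seq_len(n_target)]

  # 99th percentile of the control prior's Beta marginal, per category
  marg99 <- qbeta(0.99, concentration / K, concentration * (K - 1) / K)

  with_preserved_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n_control + n_target)
    g <- matrix(rgamma(n_control * K, shape = concentration / K),
                nrow = n_control)
    control_probs <- g / rowSums(g)
    control_rates <- runif(n_control, 0.04, 0.12)
    target_rates <- runif(n_target, 0.12, 0.15)

    specs <- vector("list", n_control + n_target)
    for (i in seq_len(n_control)) {
      specs[[i]] <- forum_spec(
        forum = sprintf("control_%03d", i), n_posts = n_posts,
        emotion_probs = setNames(control_probs[i, ], cats),
        emotion_rate = control_rates[i],
        post_length_mean = post_length_mean)
    }
    expected_outliers <- list()
    for (j in seq_along(target_defs)) {
      def <- target_defs[[j]]
      probs <- compose_probs(cats, def$elevated)
      nm <- names(target_defs)[j]
      specs[[n_control + j]] <- forum_spec(
        forum = nm, n_posts = n_posts, emotion_probs = probs,
        emotion_rate = target_rates[j],
        post_length_mean = post_length_mean,
        abstinence = def$abstinence)
      mp <- marginal_probs(specs[[n_control + j]])
      expected_outliers[[nm]] <- cats[mp > marg99]
    }

    out <- lapply(seq_along(specs), function(i) {
      generate_corpus(specs[[i]], lex, seed = sub_seeds[i])
    })
    posts <- dplyr::bind_rows(lapply(out, `[[`, "posts"))
    truth <- dplyr::bind_rows(lapply(seq_along(out), function(i) {
      tibble(forum = specs[[i]]$forum,
             category = cats,
             prob = unname(marginal_probs(specs[[i]])[cats]),
             count = out[[i]]$truth$counts$count)
    }))
    res <- list(
      posts = posts, specs = specs, truth = truth,
      expected_outliers = expected_outliers,
      control_forums = vapply(specs[seq_len(n_control)], `[[`, "", "forum"),
      target_forums = names(target_defs)
    )
    if (!is.null(write_dir)) {
      dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
      write_posts_jsonl(posts, file.path(write_dir, "posts.jsonl"))
      write.csv(as.data.frame(truth), file.path(write_dir, "truth.csv"),
                row.names = FALSE)
    }
    res
  })
}

#' Simulate a per-bin-normalised emotion table directly
#'
#' Draws each bin's category counts from a multinomial and normalises per
#' bin, skipping text generation. Useful for null-calibration studies
#' (same composition in both abstinence levels) and for exercising the
#' ANOVA on arbitrary normalised tables.
#'
#' @param lex A [lexicon()] (supplies the category set).
#' @param bins An [abstinence_bins()] table.
#' @param matches_per_bin Lexicon matches drawn per bin. Default 250.
#' @param probs_short,probs_long Named compositions for short/long bins;
#'   default uniform, and `probs_long` defaults to `probs_short` (a null
#'   table).
#' @param seed Optional integer seed.
#' @return A `cessalex_binned` table (see [bin_posts()]).
#' @export
simulate_binned_table <- function(lex, bins = abstinence_bins(),
                                  matches_per_bin = 250,
                                  probs_short = NULL, probs_long = NULL,
                                  seed = NULL) {
  stopifnot(inherits(lex, "cessalex_lexicon"), inherits(bins, "cessalex_bins"))
  cats <- lexicon_categories(lex)
  K <- length(cats)
  if (is.null(probs_short)) probs_short <- setNames(rep(1 / K, K), cats)
  if (is.null(probs_long)) probs_long <- probs_short
  with_preserved_seed(seed, {
    n_short <- sum(bins$level == "short")
    cnt <- cbind(
      rmultinom(n_short, matches_per_bin, probs_short[cats]),
      rmultinom(nrow(bins) - n_short, matches_per_bin, probs_long[cats])
    )
    out <- tibble(
      bin = rep(bins$bin, each = K),
      level = rep(bins$level, each = K),
      category = rep(cats, times = nrow(bins)),
      count = as.integer(cnt),
      frequency = 100 * as.vector(cnt) / matches_per_bin
    )
    structure(
      out,
      n_posts = rep(NA_integer_, nrow(bins)),
      bin_matches = rep(matches_per_bin, nrow(bins)),
      bins = bins, lex_name = attr(lex, "lex_name"), categories = cats,
      field = "body",
      class = c("cessalex_binned", class(out))
    )
  })
}
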