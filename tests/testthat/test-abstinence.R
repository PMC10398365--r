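# Minimal binned table carrying just the values a post-hoc contrast needs.
toy_binned <- function(short_vals, long_vals, emotion = "anxiety") {
  lex <- default_emotion_lexicon()
  bins <- abstinence_bins(n_short = max(2, length(short_vals)),
                          n_long = max(1, length(long_vals)))
  df <- tibble::tibble(
    bin = seq_len(length(short_vals) + length(long_vals)),
    level = rep(c("short", "long"), c(length(short_vals), length(long_vals))),
    category = emotion,
    count = NA_integer_,
    frequency = c(short_vals, long_vals)
  )
  structure(df, bins = bins, lex_name = "emotion",
            categories = lexicon_categories(lex),
            bin_matches = rep(1, nrow(df)), n_posts = rep(1L, nrow(df)),
            field = "body",
            class = c("cessalex_binned", class(df)))
}

test_that("default bins: 15 log-spaced bins, 9 short below 100, closed at 1000", {
  bins <- abstinence_bins()
  edges <- attr(bins, "edges")
  expect_equal(nrow(bins), 15)
  expect_equal(length(edges), 16)
  expect_equal(edges[1], 0)
  expect_equal(edges[2], 1)
  expect_equal(edges[10], 100) # index 9, 0-based
  expect_equal(edges[16], 1000)
  expect_equal(sum(bins$level == "short"), 9)
  expect_equal(sum(bins$level == "long"), 6)
  expect_true(all(bins$upper[bins$level == "short"] <= 100))
  expect_true(all(bins$lower[bins$level == "long"] >= 100))
  expect_true(all(diff(edges) > 0))
})

test_that("posts land in half-open bins with the final bin closed at the cutoff", {
  lex <- toy_lexicon()
  days <- c(0, 0.99, 1, 99.9, 100, 999, 1000, 1001)
  posts <- make_posts(rep("proud", length(days)), abstinence_days = days)
  binned <- bin_posts(posts, lex)
  n_posts <- attr(binned, "n_posts")
  expect_equal(sum(n_posts), 7)  # day 1001 excluded
  expect_equal(n_posts[1], 2)    # days 0 and 0.99; day 1 opens bin 2
  expect_equal(n_posts[15], 2)   # day 999 and the closed edge at 1000
})

test_that("bin membership around the edges is exact", {
  lex <- toy_lexicon()
  probe <- function(day) {
    posts <- make_posts("proud", abstinence_days = day)
    which(attr(bin_posts(posts, lex), "n_posts") == 1L)
  }
  expect_equal(probe(0), 1L)
  expect_equal(probe(0.5), 1L)
  expect_equal(probe(1), 2L)
  expect_equal(probe(99.9), 9L)
  expect_equal(probe(100), 10L)
  expect_equal(probe(1000), 15L)
  posts_out <- make_posts("proud", abstinence_days = 1001)
  expect_equal(sum(attr(bin_posts(posts_out, lex), "n_posts")), 0L)
})

test_that("abstinence-tagged filtering keeps recent tagged text posts", {
  posts <- make_posts(c(rep("words here", 8), "", "words"),
                      abstinence_days = c(1:8, 2, NA))
  out <- filter_abstinence_tagged(posts, n_keep = 5)
  expect_equal(nrow(out), 5)
  expect_true(all(!is.na(out$abstinence_days)))
  # newest-first fixture: first five tagged text posts are kept
  expect_equal(out$abstinence_days, 1:5)

  expect_warning(all_of_them <- filter_abstinence_tagged(posts, n_keep = 50),
                 "returning all")
  expect_equal(nrow(all_of_them), 8)
  expect_warning(none <- filter_abstinence_tagged(make_posts("x"), n_keep = 5),
                 "no abstinence-tagged")
  expect_equal(nrow(none), 0)
})

test_that("first-day fraction and its uniform chance level", {
  posts <- make_posts(rep("w", 100),
                      abstinence_days = c(rep(0.5, 7), rep(10, 93)))
  expect_equal(first_day_fraction(posts), 7.0)
  posts_none <- make_posts(rep("w", 10), abstinence_days = rep(5, 10))
  expect_equal(first_day_fraction(posts_none), 0.0)
  posts_all <- make_posts(rep("w", 10), abstinence_days = rep(0.1, 10))
  expect_equal(first_day_fraction(posts_all), 100.0)
  expect_error(first_day_fraction(make_posts(character(0))), "no posts")

  expect_identical(uniform_chance_first_day(10000), 0.01)
  expect_identical(uniform_chance_first_day(100), 1.0)
  expect_identical(uniform_chance_first_day(1), 100.0)
  expect_error(uniform_chance_first_day(0.5), "at least 1")
})

test_that("first-day profile recovers the dominant simulated emotions", {
  lex <- default_emotion_lexicon()
  probs <- uniform_probs(lex)
  probs[] <- (1 - 0.3 - 0.25) / (length(probs) - 2)
  probs["anxiety"] <- 0.3
  probs["optimism"] <- 0.25
  spec <- forum_spec("f", n_posts = 600, emotion_probs = probs,
                     emotion_rate = 0.5, post_length_mean = 25,
                     abstinence = list(day0_mass = 0.5))
  g <- generate_corpus(spec, lex, seed = 410)
  prof <- first_day_profile(g$posts, lex, top_m = 5)
  expect_equal(attr(prof, "top_categories")[1:2], c("anxiety", "optimism"))
  expect_equal(sum(prof$frequency), 100, tolerance = 1e-9)

  single <- make_posts("proud", abstinence_days = 0.2)
  sp <- first_day_profile(single, toy_lexicon(), top_m = 1)
  expect_equal(sp$frequency[sp$category == "pride"], 100)
  late <- make_posts("proud", abstinence_days = 5)
  expect_error(first_day_profile(late, toy_lexicon()), "first 24 hours")
})

test_that("every non-empty bin's percentages sum to 100", {
  lex <- default_emotion_lexicon()
  spec <- forum_spec("f", n_posts = 800, emotion_probs = uniform_probs(lex),
                     emotion_rate = 0.3, post_length_mean = 15,
                     abstinence = list())
  g <- generate_corpus(spec, lex, seed = 411)
  binned <- bin_posts(g$posts, lex)
  sums <- tapply(binned$frequency, binned$bin, sum)
  nonempty <- attr(binned, "bin_matches") > 0
  expect_equal(as.numeric(sums[nonempty]), rep(100, sum(nonempty)),
               tolerance = 1e-9)
})

test_that("two-way ANOVA has the standard df and a forced-zero abstinence effect", {
  lex <- default_emotion_lexicon()
  tab <- simulate_binned_table(lex, seed = 412)
  g <- glance(two_way_anova(tab))
  expect_equal(g$df_emotion, 20)
  expect_equal(g$df_abstinence, 1)
  expect_equal(g$df_interaction, 20)
  expect_equal(g$df_residual, 21 * 15 - 42)
  expect_lt(abs(g$f_abstinence), 1e-8)

  # holds for any per-bin-normalised table, including skewed compositions
  set.seed(413)
  for (i in 1:4) {
    pr <- stats::runif(21); pr <- stats::setNames(pr / sum(pr),
                                                  lexicon_categories(lex))
    tab_i <- simulate_binned_table(lex, matches_per_bin = 120,
                                   probs_short = pr, probs_long = pr)
    expect_lt(abs(glance(two_way_anova(tab_i))$f_abstinence), 1e-8)
  }
})

test_that("ANOVA errors name empty bins and is invariant to row order", {
  lex <- toy_lexicon()
  posts <- make_posts(rep("proud", 3), abstinence_days = c(0, 50, 500))
  binned <- bin_posts(posts, lex)
  expect_error(two_way_anova(binned), "no lexicon matches")

  tab <- simulate_binned_table(default_emotion_lexicon(), seed = 414)
  shuffled <- tab[sample.int(nrow(tab)), ]
  attributes(shuffled) <- c(attributes(shuffled),
                            attributes(tab)[c("bins", "lex_name",
                                              "categories", "bin_matches",
                                              "n_posts", "field")])
  class(shuffled) <- class(tab)
  expect_equal(tidy(two_way_anova(shuffled))$statistic,
               tidy(two_way_anova(tab))$statistic, tolerance = 1e-10)
})

test_that("a composition shift in long bins surfaces as interaction, not main effect", {
  lex <- default_emotion_lexicon()
  cats <- lexicon_categories(lex)
  ps <- uniform_probs(lex)
  pl <- ps; pl["anxiety"] <- ps["anxiety"] * 0.3; pl <- pl / sum(pl)
  tab <- simulate_binned_table(lex, matches_per_bin = 400,
                               probs_short = ps, probs_long = pl, seed = 415)
  fit <- glance(two_way_anova(tab))
  expect_lt(abs(fit$f_abstinence), 1e-8)

  # permutation null: reassign which bins are long; observed F beats it
  obs <- fit$f_interaction
  set.seed(416)
  perm_f <- replicate(99, {
    long_bins <- sample(1:15, 6)
    tab_p <- tab
    tab_p$level <- ifelse(tab_p$bin %in% long_bins, "long", "short")
    glance(two_way_anova(tab_p))$f_interaction
  })
  expect_gt(obs, stats::quantile(perm_f, 0.95))
})

test_that("pooled post-hoc t matches the hand-computed toy example", {
  tb <- toy_binned(short_vals = c(5, 6, 7), long_vals = c(1, 2, 3))
  res <- posthoc_ttests(tb, "anxiety", alpha = 0.05)
  expect_equal(res$statistic, 4.899, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$estimate, 4)

  # cross-check against the closed-form pooled t
  sp2 <- (2 * stats::var(c(5, 6, 7)) + 2 * stats::var(c(1, 2, 3))) / 4
  t_manual <- 4 / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
})

test_that("post-hoc df is n1+n2-2 for the 9-vs-6 design and Bonferroni applies", {
  lex <- default_emotion_lexicon()
  tab <- simulate_binned_table(lex, seed = 417)
  emos <- c("anxiety", "disgust", "pride", "gratitude")
  res <- posthoc_ttests(tab, emos)
  expect_equal(res$df, rep(13, 4))
  expect_equal(res$alpha_bonferroni, rep(0.05 / 4, 4))
  expect_equal(res$significant, res$p.value < 0.0125)

  welch <- posthoc_ttests(tab, emos, var_equal = FALSE)
  expect_false(all(welch$df == 13))
  expect_error(posthoc_ttests(tab, "not_a_category"), "not in lexicon")
})

test_that("degenerate constant data yields t = 0, p = 1", {
  tb <- toy_binned(short_vals = rep(4, 3), long_vals = rep(4, 3))
  res <- posthoc_ttests(tb, "anxiety")
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
})
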