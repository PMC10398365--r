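test_that("forum specs validate their simplex and fractions", {
  lex <- toy_lexicon()
  bad <- uniform_probs(lex); bad[1] <- bad[1] + 0.5
  expect_error(forum_spec("f", emotion_probs = bad), "simplex")
  expect_error(forum_spec("f", emotion_probs = c(0.5, 0.5)), "named")
  ok <- forum_spec("f", emotion_probs = uniform_probs(lex))
  expect_s3_class(ok, "cessalex_forum_spec")
})

test_that("generation is bit-identical under a fixed seed and leaves the RNG alone", {
  lex <- toy_lexicon()
  spec <- forum_spec("f", n_posts = 60, emotion_probs = uniform_probs(lex),
                     emotion_rate = 0.3, post_length_mean = 10,
                     abstinence = list())
  set.seed(418); sentinel_before <- stats::runif(1)
  set.seed(418)
  g1 <- generate_corpus(spec, lex, seed = 5)
  sentinel_after <- stats::runif(1)
  g2 <- generate_corpus(spec, lex, seed = 5)
  expect_identical(g1, g2)
  expect_identical(sentinel_before, sentinel_after)

  g3 <- generate_corpus(spec, lex, seed = 6)
  expect_false(identical(g1$posts$body, g3$posts$body))
})

test_that("recounting generated text reproduces the truth record exactly", {
  lex <- default_emotion_lexicon()
  set.seed(419)
  for (i in 1:3) {
    probs <- stats::runif(21)
    probs <- stats::setNames(probs / sum(probs), lexicon_categories(lex))
    spec <- forum_spec("f", n_posts = 150, emotion_probs = probs,
                       emotion_rate = stats::runif(1, 0.05, 0.4),
                       post_length_mean = 20)
    g <- generate_corpus(spec, lex, seed = 420 + i)
    recount <- count_matches(preprocess_text(g$posts$body), lex)
    expect_identical(recount$count, g$truth$counts$count)
    # titles are filler-only, so field choice cannot change the counts
    both <- count_matches(
      preprocess_text(paste(g$posts$title, g$posts$body)), lex)
    expect_identical(both$count, g$truth$counts$count)
  }
})

test_that("filler vocabulary is disjoint from the shipped banks by prefix", {
  filler <- filler_vocabulary()
  expect_false(any(filler %in% default_emotion_lexicon()$word))
  expect_false(any(filler %in% default_time_lexicon()$word))
  expect_identical(preprocess_text(paste(filler, collapse = " ")), filler)
})

test_that("image-only fraction produces empty bodies that fail inclusion", {
  lex <- toy_lexicon()
  spec <- forum_spec("f", n_posts = 80, emotion_probs = uniform_probs(lex),
                     image_only_frac = 1)
  g <- generate_corpus(spec, lex, seed = 421)
  expect_true(all(g$posts$body == ""))
  expect_false(passes_inclusion(g$posts, min_text = 40, window = 80))

  spec2 <- forum_spec("f", n_posts = 400, emotion_probs = uniform_probs(lex),
                      image_only_frac = 0.3)
  g2 <- generate_corpus(spec2, lex, seed = 422)
  frac <- mean(g2$posts$body == "")
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 400))
})

test_that("pipeline profile recovers a concentrated composition within 3 SE", {
  lex <- default_emotion_lexicon()
  probs <- uniform_probs(lex)
  probs[] <- (1 - 0.6) / (length(probs) - 1)
  probs["pride"] <- 0.6
  spec <- forum_spec("f", n_posts = 3003, emotion_probs = probs,
                     emotion_rate = 0.05, post_length_mean = 12)
  g <- generate_corpus(spec, lex, seed = 423)
  prof <- corpus_profile(g$posts, lex)
  total <- attr(prof, "totals")[["f"]]
  expect_gt(total, 1000)
  se <- 100 * sqrt(0.6 * 0.4 / total)
  expect_lt(abs(prof$frequency[prof$category == "pride"] - 60), 3 * se)
})

test_that("first-day posting mass converges to the configured point mass", {
  lex <- toy_lexicon()
  spec <- forum_spec("f", n_posts = 4000, emotion_probs = uniform_probs(lex),
                     post_length_mean = 3, abstinence = list(day0_mass = 0.07))
  g <- generate_corpus(spec, lex, seed = 424)
  days <- g$posts$abstinence_days
  expect_true(all(!is.na(days)))
  expect_lt(abs(mean(days < 1) - 0.07), 3 * sqrt(0.07 * 0.93 / 4000))
  expect_true(max(days) <= 10000)
  # heavy right tail: some posts beyond 1000 days
  expect_gt(mean(days > 1000), 0)
})

test_that("post-100-day shift changes composition only in long-duration posts", {
  lex <- default_emotion_lexicon()
  probs <- uniform_probs(lex)
  spec <- forum_spec("f", n_posts = 2500, emotion_probs = probs,
                     emotion_rate = 0.5, post_length_mean = 20,
                     abstinence = list(post100_shift = c(anxiety = -0.04)))
  g <- generate_corpus(spec, lex, seed = 425)
  short_tot <- sum(g$truth$counts_short$count)
  long_tot <- sum(g$truth$counts_long$count)
  p_short <- g$truth$counts_short$count[
    g$truth$counts_short$category == "anxiety"] / short_tot
  p_long <- g$truth$counts_long$count[
    g$truth$counts_long$category == "anxiety"] / long_tot
  p0 <- 1 / 21
  shifted <- (p0 - 0.04) / (1 - 0.04)
  expect_lt(abs(p_short - p0), 3 * sqrt(p0 * (1 - p0) / short_tot))
  expect_lt(abs(p_long - shifted), 3 * sqrt(shifted * (1 - shifted) / long_tot))
})

test_that("study bundles have the expected composition and determinism", {
  s1 <- generate_study(n_control = 6, n_target = 3, seed = 426, n_posts = 40)
  expect_equal(length(unique(s1$posts$forum)), 9)
  expect_equal(nrow(s1$posts), 9 * 40)
  expect_setequal(s1$target_forums,
                  c("cess_alcohol", "cess_nicotine", "cess_cannabis"))
  expect_true(all(c("anxiety") %in% unlist(s1$expected_outliers)))
  s2 <- generate_study(n_control = 6, n_target = 3, seed = 426, n_posts = 40)
  expect_identical(s1$posts, s2$posts)

  # bundle written to disk reads back through the standard reader
  dir <- withr::local_tempdir()
  s3 <- generate_study(n_control = 2, n_target = 1, seed = 427, n_posts = 15,
                       write_dir = dir)
  back <- read_posts_jsonl(file.path(dir, "posts.jsonl"))
  expect_equal(nrow(back), nrow(s3$posts))
  expect_equal(back$body, s3$posts$body)
})

test_that("null binned tables are balanced draws from one composition", {
  lex <- default_emotion_lexicon()
  tab <- simulate_binned_table(lex, matches_per_bin = 200, seed = 428)
  expect_equal(nrow(tab), 21 * 15)
  sums <- tapply(tab$count, tab$bin, sum)
  expect_true(all(sums == 200))
  expect_equal(as.numeric(tapply(tab$frequency, tab$bin, sum)),
               rep(100, 15), tolerance = 1e-9)
})
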