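# Small fixtures built in code; no files on disk.

toy_lexicon <- function() {
  lexicon(
    tibble::tibble(
      category = c("pride", "pride", "anxiety", "anxiety", "joy"),
      word = c("proud", "pride", "anxious", "nervous", "happy")
    ),
    name = "toy"
  )
}

make_posts <- function(bodies, forum = "f", titles = NULL, authors = NULL,
                       abstinence_days = NA_real_, newest_first = TRUE) {
  n <- length(bodies)
  ts <- if (newest_first) seq(1e9, by = -60, length.out = n) else
    seq(1e9 - 60 * (n - 1), by = 60, length.out = n)
  tibble::tibble(
    forum = forum,
    author = authors %||% paste0("u", seq_len(n)),
    created_utc = ts,
    title = titles %||% rep("t", n),
    body = bodies,
    abstinence_days = abstinence_days
  )
}

uniform_probs <- function(lex) {
  cats <- lexicon_categories(lex)
  stats::setNames(rep(1 / length(cats), length(cats)), cats)
}

`%||%` <- rlang::`%||%`
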