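#' Build a lexicon from category/word pairs
#'
#' A lexicon is a tibble with columns `category` and `word` plus a fixed,
#' reproducible category order (the order of first appearance), which
#' defines the dimension order of every frequency vector built from it.
#' Words are normalised through [preprocess_text()] so that every lexicon
#' word is a fixed point of the preprocessing applied to post text.
#'
#' @param data A data frame with columns `category` and `word`.
#' @param name Short identifier for the lexicon.
#'
#' @return A tibble of class `cessalex_lexicon` with attributes `lex_name`
#'   and `categories` (ordered character vector).
#' @export
lexicon <- function(data, name = "lexicon") {
  if (!all(c("category", "word") %in% names(data))) {
    abort("`data` must have columns `category` and `word`.")
  }
  if (nrow(data) == 0L) {
    abort("lexicon is empty: no (category, word) records supplied.")
  }
  cat_order <- unique(as.character(data$category))
  raw_words <- as.character(data$word)
  norm <- preprocess_text(raw_words, collapse = FALSE)
  n_tok <- lengths(norm)
  if (any(n_tok == 0L)) {
    bad <- raw_words[n_tok == 0L][1L]
    abort(paste0("lexicon word normalises to nothing: ", encodeString(bad, quote = '"')))
  }
  if (any(n_tok > 1L)) {
    bad <- raw_words[n_tok > 1L][1L]
    abort(paste0("multi-token lexicon entry (single tokens only): ",
                 encodeString(bad, quote = '"')))
  }
  out <- tibble(
    category = as.character(data$category),
    word = unlist(norm, use.names = FALSE)
  )
  out <- dplyr::distinct(out, .data$category, .data$word)
  out <- dplyr::arrange(out, match(.data$category, cat_order))
  dup <- out$word[duplicated(out$word)]
  if (length(dup) > 0L) {
    warn(paste0("lexicon words shared across categories: ",
                paste(unique(dup), collapse = ", ")))
  }
  structure(
    as_tibble(out),
    lex_name = name,
    categories = cat_order,
    class = c("cessalex_lexicon", class(as_tibble(out)))
  )
}

#' @export
print.cessalex_lexicon <- function(x, ...) {
  cat(sprintf("<cessalex_lexicon> %s: %d categories, %d words\n",
              attr(x, "lex_name"), length(attr(x, "categories")), nrow(x)))
  NextMethod()
}

#' Number and order of lexicon categories
#'
#' @param lex A [lexicon()].
#' @return `lexicon_categories()` returns the ordered character vector of
#'   category names; `lexicon_size()` returns its length (K).
#' @export
lexicon_categories <- function(lex) {
  stopifnot(inherits(lex, "cessalex_lexicon"))
  attr(lex, "categories")
}

#' @rdname lexicon_categories
#' @export
lexicon_size <- function(lex) length(lexicon_categories(lex))

#' Read a lexicon from CSV or JSON
#'
#' CSV dialect: two columns `category,word`, UTF-8, header row required.
#' JSON dialect: an object mapping category name to an array of words.
#' Duplicate (category, word) pairs are collapsed; words are lowercased and
#' must be single tokens.
#'
#' @param path Path to the lexicon file.
#' @param format `"csv"` or `"json"`; guessed from the file extension by
#'   default.
#' @param name Identifier for the lexicon; defaults to the file name.
#' @return A [lexicon()].
#' @export
read_lexicon <- function(path, format = c("auto", "csv", "json"),
                         name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("lexicon file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "csv") {
    if (file.size(path) == 0L) abort(paste0("empty lexicon file: ", path))
    df <- read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
    if (nrow(df) == 0L) abort(paste0("empty lexicon file: ", path))
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (length(obj) == 0L) abort(paste0("empty lexicon file: ", path))
    df <- tibble(
      category = rep(names(obj), lengths(obj)),
      word = unlist(obj, use.names = FALSE)
    )
  }
  lexicon(df, name = name)
}

#' Write a lexicon to CSV or JSON
#'
#' Round-trips through [read_lexicon()]: category order and word sets are
#' preserved exactly.
#'
#' @param lex A [lexicon()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(lex, "cessalex_lexicon"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    write.csv(as.data.frame(lex[c("category", "word")]), path,
              row.names = FALSE, fileEncoding = "UTF-8", quote = FALSE)
  } else {
    words <- split(lex$word, factor(lex$category, levels = lexicon_categories(lex)))
    jsonlite::write_json(words, path)
  }
  invisible(path)
}

#' Default 21-category emotion word bank
#'
#' A curated bank of 21 emotion categories built around Plutchik's primary
#' and secondary emotions plus clinically salient additions (anxiety, pride,
#' gratitude, terror, remorse, ...). The word lists are the package's own
#' curation; every pipeline stage accepts a user-supplied lexicon instead.
#'
#' @return A [lexicon()] with K = 21 categories, including `anxiety`,
#'   `sadness`, `optimism`, `joy`, `love`, `disgust`, `pride`, `gratitude`,
#'   `remorse`, `terror` and `fear`.
#' @export
default_emotion_lexicon <- function() {
  path <- system.file("extdata", "emotion_lexicon.csv", package = "cessalex",
                      mustWork = TRUE)
  read_lexicon(path, format = "csv", name = "emotion")
}

#' Default 15-category time word bank
#'
#' A control bank of 15 time-of-day and duration categories (morning,
#' afternoon, ..., day, week, month, year, ...), used to check that results
#' obtained with the emotion bank are emotion-specific rather than generic
#' lexical artefacts.
#'
#' @return A [lexicon()] with K = 15 categories, including `morning`.
#' @export
default_time_lexicon <- function() {
  path <- system.file("extdata", "time_lexicon.csv", package = "cessalex",
                      mustWork = TRUE)
  read_lexicon(path, format = "csv", name = "time")
}
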