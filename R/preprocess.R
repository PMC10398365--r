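#' Normalise raw post text into a token stream
#'
#' Applies the normalisation used throughout the package, in this order:
#' markup tags of the form `<...>` are removed first, every punctuation or
#' symbol character is replaced by a space, letters are lowercased, and the
#' result is split on runs of whitespace. Numerals are retained by default.
#'
#' Replacing punctuation by a space (rather than deleting it) means
#' contractions split: `"don't"` yields tokens `"don"`, `"t"`. Tag removal
#' precedes punctuation stripping so that `<b>` cannot leak a stray `b`
#' token.
#'
#' @param raw Character vector of raw text (each element is tokenised
#'   independently when `collapse = FALSE`).
#' @param strip_numerals Drop tokens consisting entirely of digits.
#'   Default `FALSE`.
#' @param min_token_len Drop tokens shorter than this many characters.
#'   Default `1` (keep everything).
#' @param collapse If `TRUE` (default) return a single character vector of
#'   tokens pooled over all elements of `raw`; if `FALSE` return a list of
#'   token vectors, one per element.
#'
#' @return A character vector of lowercase, punctuation-free tokens (or a
#'   list of such vectors). Empty input yields a zero-length vector.
#'
#' @examples
#' preprocess_text("<b>Proud</b> today!!!")
#' preprocess_text("I'm SO  anxious")
#' preprocess_text("60 days sober")
#' @export
preprocess_text <- function(raw, strip_numerals = FALSE, min_token_len = 1L,
                            collapse = TRUE) {
  if (length(raw) == 0L) {
    return(if (collapse) character(0) else list())
  }
  raw[is.na(raw)] <- ""
  x <- gsub("<[^>]*>", " ", raw, perl = TRUE)
  # Unicode punctuation + symbols -> space; keeps letters and numerals
  x <- gsub("[\\p{P}\\p{S}]", " ", x, perl = TRUE)
  x <- tolower(x)
  toks <- strsplit(trimws(x), "\\s+", perl = TRUE)
  toks <- lapply(toks, function(t) t[nzchar(t)])
  if (strip_numerals) {
    toks <- lapply(toks, function(t) t[!grepl("^[0-9]+$", t)])
  }
  if (min_token_len > 1L) {
    toks <- lapply(toks, function(t) t[nchar(t) >= min_token_len])
  }
  if (collapse) unlist(toks, use.names = FALSE) else toks
}
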