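#' Cosine similarity between two frequency vectors
#'
#' Returns u.v / (||u|| ||v||). For nonnegative occurrence-frequency
#' vectors the value lies in [0, 1]; it is invariant to positive rescaling
#' of either vector, so percentages and raw counts give the same answer.
#'
#' @param u,v Numeric vectors of equal length with positive norm.
#' @return A single number.
#' @examples
#' cosine_similarity(c(1, 0, 0), c(1, 1, 0)) # 1/sqrt(2)
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) abort("vectors differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Pairwise cosine-similarity matrix over forum profiles
#'
#' Builds each forum's K-dimensional occurrence-frequency vector (category
#' order fixed by the lexicon) and computes all pairwise cosine
#' similarities.
#'
#' @param profiles A [corpus_profile()] covering two or more forums.
#' @return An object of class `cessalex_simmat`: a symmetric matrix with
#'   unit diagonal, forum names on both dimnames, and attribute
#'   `lex_name`. Use [tidy()] for a long tibble.
#' @export
similarity_matrix <- function(profiles) {
  if (!inherits(profiles, "cessalex_profile")) {
    abort("`profiles` must be a cessalex_profile")
  }
  cats <- attr(profiles, "categories")
  wide <- profiles |>
    as_tibble() |>
    dplyr::select("forum", "category", "frequency") |>
    tidyr::pivot_wider(names_from = "category", values_from = "frequency")
  if (nrow(wide) < 2L) abort("need at least 2 forums for a similarity matrix")
  m <- as.matrix(wide[, cats, drop = FALSE])
  rownames(m) <- wide$forum
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) abort("zero profile vector: cosine similarity undefined")
  unit <- m / norms
  s <- tcrossprod(unit)
  s <- pmin(pmax(s, 0), 1)
  diag(s) <- 1
  structure(s, lex_name = attr(profiles, "lex_name"),
            class = c("cessalex_simmat", "matrix", "array"))
}

#' @export
print.cessalex_simmat <- function(x, ...) {
  cat(sprintf("<cessalex_simmat> %d forums, lexicon %s\n",
              nrow(x), attr(x, "lex_name")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

#' @describeIn similarity_matrix Long tibble of pairwise similarities
#'   (columns `forum_a`, `forum_b`, `similarity`).
#' @param x A `cessalex_simmat`.
#' @param ... Unused.
#' @method tidy cessalex_simmat
#' @export
tidy.cessalex_simmat <- function(x, ...) {
  tibble(
    forum_a = rep(rownames(x), times = ncol(x)),
    forum_b = rep(colnames(x), each = nrow(x)),
    similarity = as.vector(unclass(x))
  )
}

#' Most emotionally similar forums to a target
#'
#' Ranks the non-self forums by cosine similarity to the target,
#' descending; ties are broken lexicographically by forum name so results
#' are reproducible across runs and snapshots.
#'
#' @param simmat A [similarity_matrix()].
#' @param target Forum name present in the matrix.
#' @param k Number of neighbours. Default 5.
#' @return A tibble with columns `rank`, `forum`, `similarity`.
#' @export
top_k_similar <- function(simmat, target, k = 5) {
  stopifnot(inherits(simmat, "cessalex_simmat"))
  forums <- rownames(simmat)
  if (!target %in% forums) abort(paste0("forum not in matrix: ", target))
  if (k >= length(forums)) abort("k must be smaller than the number of forums")
  others <- setdiff(forums, target)
  sims <- unclass(simmat)[target, others]
  ord <- order(-sims, others)[seq_len(k)]
  tibble(rank = seq_len(k), forum = others[ord],
         similarity = unname(sims[ord]))
}
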