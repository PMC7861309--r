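#' Normalise an ingredient or token name
#'
#' Lowercases, trims, and collapses internal whitespace. All joins between
#' tables (ingredient names, review phrases, embedding vocabularies) go
#' through this normal form; the raw name is kept for display.
#'
#' @param x Character vector of names.
#' @return Character vector of normalised names.
#' @export
#' @examples
#' normalize_name("  Red  Onion ")
normalize_name <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Cosine similarity between two numeric vectors
#'
#' Returns 0 (not NaN) when either vector has zero norm, the convention used
#' by every similarity score in the package.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A single number in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    return(0)
  }
  sum(a * b) / (na * nb)
}

abort_format <- function(msg) {
  rlang::abort(msg, class = "substkg_format_error")
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "substkg_validation_error")
}

abort_lookup <- function(msg) {
  rlang::abort(msg, class = "substkg_lookup_error")
}

abort_parameter <- function(msg) {
  rlang::abort(msg, class = "substkg_parameter_error")
}

# Tokeniser shared by the embedding corpus and the review miner: lowercase,
# keep alphanumeric runs (so "tsp" and "100" both survive).
tokenize_text <- function(x) {
  x <- tolower(x)
  toks <- strsplit(x, "[^a-z0-9']+")
  lapply(toks, function(t) t[nzchar(t)])
}
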