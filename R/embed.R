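#' Train a name/instruction embedding over a recipe corpus
#'
#' Learns one vector per token from the corpus formed by concatenating, for
#' each recipe, its ingredient names and its instruction text. Token vectors
#' are obtained by truncated SVD of the windowed token-token PPMI matrix --
#' the implicit matrix-factorisation objective of skip-gram with negative
#' sampling -- which makes training exactly reproducible for a fixed corpus.
#' Ingredients used in interchangeable recipe contexts end up with high
#' cosine similarity between their name vectors.
#'
#' @param recipes Recipe tibble (see [load_recipes()]).
#' @param ingredients Ingredient table used to resolve names.
#' @param dim Embedding dimension (capped at the vocabulary size).
#' @param window Symmetric context window in tokens.
#' @param min_count Minimum token frequency to enter the vocabulary.
#' @param seed Integer seed, recorded in the model metadata.
#' @return An `embedding_model`.
#' @export
train_corpus_embedding <- function(recipes, ingredients, dim = 64,
                                   window = 5, min_count = 1, seed = 1) {
  if (nrow(recipes) == 0) abort_parameter("empty recipe corpus")
  if (dim <= 0) abort_parameter("embedding dimension must be positive")
  sentences <- corpus_sentences(recipes, ingredients)
  sentences <- sentences[lengths(sentences) > 0]
  if (length(sentences) == 0) abort_parameter("corpus has no usable tokens")

  counts <- window_cooccurrence(sentences, window)
  freq <- Matrix::rowSums(counts)
  keep <- names(freq)[freq >= min_count]
  counts <- counts[keep, keep, drop = FALSE]

  vec <- ppmi_svd_vectors(counts, dim)
  embedding_model(vec, metadata = list(
    method = "ppmi-svd", window = window, min_count = min_count, seed = seed
  ))
}

corpus_sentences <- function(recipes, ingredients) {
  name_of <- stats::setNames(ingredients$name, ingredients$ingredient_id)
  purrr::map(seq_len(nrow(recipes)), function(k) {
    ids <- recipes$ingredients[[k]]$ingredient_id
    text <- paste(
      paste(name_of[ids], collapse = " "),
      recipes$instructions[[k]]
    )
    tokenize_text(text)[[1]]
  })
}

# Symmetric windowed co-occurrence counts as a sparse token x token matrix.
window_cooccurrence <- function(sentences, window) {
  vocab <- sort(unique(unlist(sentences, use.names = FALSE)))
  idx <- stats::setNames(seq_along(vocab), vocab)
  ii <- integer(0)
  jj <- integer(0)
  for (s in sentences) {
    n <- length(s)
    if (n < 2) next
    si <- idx[s]
    for (p in seq_len(n - 1)) {
      q <- seq(p + 1, min(n, p + window))
      ii <- c(ii, rep.int(si[p], length(q)), si[q])
      jj <- c(jj, si[q], rep.int(si[p], length(q)))
    }
  }
  Matrix::sparseMatrix(
    i = ii, j = jj, x = 1,
    dims = c(length(vocab), length(vocab)),
    dimnames = list(vocab, vocab)
  )
}

ppmi_svd_vectors <- function(counts, dim) {
  total <- sum(counts)
  rs <- Matrix::rowSums(counts)
  cs <- Matrix::colSums(counts)
  m <- as.matrix(counts)
  with_counts <- m > 0
  pmi <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  pmi[with_counts] <- log(
    m[with_counts] * total /
      (outer(rs, cs)[with_counts])
  )
  pmi[pmi < 0] <- 0
  k <- min(dim, ncol(pmi))
  sv <- svd(pmi, nu = k, nv = 0)
  d <- sv$d[seq_len(k)]
  vec <- sv$u %*% diag(sqrt(pmax(d, 0)), k, k)
  # fix each singular vector's sign so factorisation output is stable
  for (j in seq_len(k)) {
    piv <- which.max(abs(vec[, j]))
    if (vec[piv, j] < 0) vec[, j] <- -vec[, j]
  }
  rownames(vec) <- rownames(pmi)
  vec
}

#' Construct an embedding model from a token-by-dimension matrix
#'
#' @param vectors Numeric matrix with one row per token; rownames are the
#'   tokens.
#' @param metadata List of training parameters kept for provenance.
#' @return An `embedding_model`.
#' @export
embedding_model <- function(vectors, metadata = list()) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  structure(
    list(
      dimension = ncol(vectors),
      vectors = vectors,
      metadata = metadata
    ),
    class = "embedding_model"
  )
}

#' @export
print.embedding_model <- function(x, ...) {
  cat("<embedding_model> ", nrow(x$vectors), " tokens x ", x$dimension,
    " dims (", x$metadata$method %||% "static", ")\n",
    sep = ""
  )
  invisible(x)
}

#' Embed a (possibly multi-word) name
#'
#' The vector of a name is the unweighted mean of the vectors of its
#' in-vocabulary tokens; a name with no in-vocabulary token maps to the zero
#' vector. Total function: never errors.
#'
#' @param model An `embedding_model`.
#' @param name Name text (normalised internally).
#' @return Numeric vector of length `model$dimension`.
#' @export
name_vector <- function(model, name) {
  toks <- tokenize_text(normalize_name(name))[[1]]
  toks <- toks[toks %in% rownames(model$vectors)]
  if (length(toks) == 0) {
    return(numeric(model$dimension))
  }
  colMeans(model$vectors[toks, , drop = FALSE])
}

#' Cosine similarity between two ingredient names under an embedding
#'
#' Cosine of the two [name_vector()]s; 0 when either name embeds to the zero
#' vector (out-of-vocabulary convention).
#'
#' @param model An `embedding_model`.
#' @param a,b Ingredient name texts.
#' @return A number in \[-1, 1\].
#' @export
name_similarity <- function(model, a, b) {
  cosine_similarity(name_vector(model, a), name_vector(model, b))
}

#' Write an embedding in word2vec text format
#'
#' First line is "count dim"; each following line is a token and its
#' components separated by spaces.
#'
#' @param model An `embedding_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_word_vectors <- function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(model$vectors), model$dimension), con)
  for (k in seq_len(nrow(model$vectors))) {
    writeLines(
      paste(
        rownames(model$vectors)[k],
        paste(formatC(model$vectors[k, ], format = "g", digits = 17),
          collapse = " "
        )
      ),
      con
    )
  }
  invisible(path)
}

#' Read an embedding from word2vec text format
#'
#' This is also the entry point for plugging in a general-language
#' (pretrained) vector table as the second name-similarity provider: any
#' file in the standard "count dim" text format works.
#'
#' @param path Path to the text file.
#' @return An `embedding_model`.
#' @export
read_word_vectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  header <- as.integer(strsplit(trimws(lines[[1]]), "[[:space:]]+")[[1]])
  if (length(header) != 2 || anyNA(header)) {
    abort_format("word2vec text format requires a 'count dim' header")
  }
  body <- lines[-1]
  if (length(body) != header[[1]]) {
    abort_format("vector count does not match header")
  }
  parts <- strsplit(body, "[[:space:]]+")
  tokens <- vapply(parts, `[[`, character(1), 1)
  vec <- t(vapply(
    parts,
    function(p) as.numeric(p[-1]),
    numeric(header[[2]])
  ))
  rownames(vec) <- tokens
  embedding_model(vec, metadata = list(method = "static"))
}
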