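#' Build the subclass-expanded recipe co-occurrence table
#'
#' For ingredients `j` and `i`, the count `T[j, i]` is the number of
#' distinct recipes containing `j` together with at least one other
#' ingredient that either is `i` or links to a class at-or-below `i`'s class
#' under `subClassOf`. The subclass expansion generalises co-occurrence: a
#' recipe using "yellow onion" also witnesses co-occurrence with the general
#' "onion" ingredient. Self pairs are excluded (`T[j, j] = 0`); an
#' ingredient never witnesses itself through its own class; duplicate
#' ingredient lines within one recipe count once.
#'
#' @param recipes Recipe tibble.
#' @param ingredients Ingredient table defining the index set of the counts.
#' @param ont A `food_ontology` (an empty ontology reduces the counts to
#'   plain pairwise recipe co-occurrence).
#' @return A `cooccurrence_table` with a sparse count matrix and the
#'   canonical ingredient index.
#' @export
build_cooccurrence <- function(recipes, ingredients, ont) {
  index <- sort(ingredients$ingredient_id)
  idx <- stats::setNames(seq_along(index), index)
  cls <- stats::setNames(ingredients$class_id, ingredients$ingredient_id)

  # ingredients whose class sits at-or-above a given class (the columns a
  # member of that class witnesses)
  class_members <- split(
    ingredients$ingredient_id[!is.na(ingredients$class_id)],
    ingredients$class_id[!is.na(ingredients$class_id)]
  )
  known <- class_ids(ont)
  witness_cache <- new.env(parent = emptyenv())
  witnessed_by_class <- function(c) {
    if (!is.null(witness_cache[[c]])) {
      return(witness_cache[[c]])
    }
    ups <- if (c %in% known) c(c, ancestors(ont, c, "subClassOf")) else c
    cols <- unlist(class_members[ups], use.names = FALSE)
    cols <- unname(idx[cols])
    witness_cache[[c]] <- cols
    cols
  }

  ii <- integer(0)
  jj <- integer(0)
  for (k in seq_len(nrow(recipes))) {
    members <- unique(recipes$ingredients[[k]]$ingredient_id)
    if (anyNA(idx[members])) {
      abort_lookup(paste0(
        "recipe '", recipes$recipe_id[[k]], "' references ingredient(s) ",
        "absent from the ingredient table: ",
        paste(members[is.na(idx[members])], collapse = ", ")
      ))
    }
    if (length(members) < 2) next
    witness <- lapply(members, function(m) {
      cols <- idx[[m]]
      if (!is.na(cls[[m]])) cols <- union(cols, witnessed_by_class(cls[[m]]))
      cols
    })
    for (a in seq_along(members)) {
      j <- idx[[members[[a]]]]
      cols <- unique(unlist(witness[-a], use.names = FALSE))
      cols <- cols[cols != j]
      if (length(cols) > 0) {
        ii <- c(ii, rep.int(j, length(cols)))
        jj <- c(jj, cols)
      }
    }
  }
  counts <- Matrix::sparseMatrix(
    i = ii, j = jj, x = 1,
    dims = c(length(index), length(index)),
    dimnames = list(index, index)
  )
  structure(
    list(counts = counts, ingredient_index = index, n_recipes = nrow(recipes)),
    class = "cooccurrence_table"
  )
}

#' @export
print.cooccurrence_table <- function(x, ...) {
  cat("<cooccurrence_table> ", length(x$ingredient_index), " ingredients, ",
    Matrix::nnzero(x$counts), " nonzero counts over ", x$n_recipes,
    " recipes\n",
    sep = ""
  )
  invisible(x)
}

#' Co-occurrence substitutability score D
#'
#' Cosine similarity between the two ingredients' co-occurrence count rows
#' over the canonical ingredient index; 0 when either row is all zero.
#' Because counts are nonnegative the score lies in \[0, 1\]. Two
#' ingredients score high when they keep the same company across recipes --
#' the signature of playing the same culinary role.
#'
#' @param table A `cooccurrence_table`.
#' @param a,b Ingredient ids in the table's index.
#' @return A number in \[0, 1\].
#' @export
cooccurrence_score <- function(table, a, b) {
  for (id in c(a, b)) {
    if (!id %in% table$ingredient_index) {
      abort_lookup(paste0("ingredient '", id, "' not in co-occurrence index"))
    }
  }
  cosine_similarity(
    as.numeric(table$counts[a, ]),
    as.numeric(table$counts[b, ])
  )
}

#' Dump nonzero co-occurrence counts to TSV
#'
#' Debug view with one row per nonzero `(j, i, count)` entry.
#'
#' @param table A `cooccurrence_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cooccurrence <- function(table, path) {
  tr <- Matrix::mat2triplet(table$counts)
  out <- tibble::tibble(
    j = table$ingredient_index[tr$i],
    i = table$ingredient_index[tr$j],
    count = as.integer(tr$x)
  )
  out <- dplyr::arrange(out, .data$j, .data$i)
  readr::write_tsv(out, path)
  invisible(path)
}
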