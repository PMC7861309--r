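#' Collect recipe-context occurrence statistics
#'
#' Ingredients are first converted to their ontology classes (so variants
#' linking to one class -- "tomatoes", "ripe tomatoes", "diced tomatoes" --
#' collapse). For each recipe and each member class `i`, the context `c` is
#' the set of the remaining members' classes; the statistics count how often
#' each class occurs (`F_i`), how often each context occurs (`F_c`), and how
#' often a class occurs with a context (`F_ic`). The focal class is
#' additionally generalised upward: every `subClassOf` ancestor of `i` is
#' also counted as occurring with `c` (contexts themselves stay literal).
#' Ingredients without a class link are skipped with a warning.
#'
#' @param recipes Recipe tibble.
#' @param ingredients Ingredient table with class links.
#' @param ont A `food_ontology`.
#' @param generalize_superclasses Count ancestors of the focal class as
#'   occurring with its contexts (default TRUE).
#' @return A `context_stats` object: counts `F_i`, `F_c`, a sparse
#'   class-by-context matrix `F_ic`, the canonical `context_index`, and the
#'   number of base counting events `n_events`.
#' @export
collect_context_stats <- function(recipes, ingredients, ont,
                                  generalize_superclasses = TRUE) {
  cls <- stats::setNames(ingredients$class_id, ingredients$ingredient_id)
  known <- class_ids(ont)
  anc_cache <- new.env(parent = emptyenv())
  ancestors_of <- function(c) {
    if (!generalize_superclasses || !(c %in% known)) {
      return(character(0))
    }
    if (is.null(anc_cache[[c]])) {
      anc_cache[[c]] <- ancestors(ont, c, "subClassOf")
    }
    anc_cache[[c]]
  }

  focal <- character(0)
  ctx <- character(0)
  n_events <- 0L
  n_skipped <- 0L
  for (k in seq_len(nrow(recipes))) {
    members <- unique(recipes$ingredients[[k]]$ingredient_id)
    classes <- unname(cls[members])
    n_skipped <- n_skipped + sum(is.na(classes))
    classes <- sort(unique(classes[!is.na(classes)]))
    if (length(classes) == 0) next
    for (i in classes) {
      key <- paste(setdiff(classes, i), collapse = "|")
      n_events <- n_events + 1L
      gen <- c(i, ancestors_of(i))
      focal <- c(focal, gen)
      ctx <- c(ctx, rep.int(key, length(gen)))
    }
  }
  if (n_events == 0L) {
    abort_validation("no recipe ingredient links to an ontology class")
  }
  if (n_skipped > 0) {
    rlang::warn(paste0(
      "skipped ", n_skipped, " recipe ingredient occurrence(s) without a class link"
    ))
  }

  class_index <- sort(unique(focal))
  context_index <- sort(unique(ctx))
  f_ic <- Matrix::sparseMatrix(
    i = match(focal, class_index),
    j = match(ctx, context_index),
    x = 1,
    dims = c(length(class_index), length(context_index)),
    dimnames = list(class_index, context_index)
  )
  f_i <- stats::setNames(as.numeric(Matrix::rowSums(f_ic)), class_index)
  # F_c counts each context once per base focal event; the generalised
  # superclass rows added to F_ic/F_i must not inflate it, so it is
  # recounted from the base events only.
  f_c <- context_base_counts(recipes, cls, known)
  f_c <- f_c[context_index]
  names(f_c) <- context_index
  structure(
    list(
      F_i = f_i, F_c = f_c, F_ic = f_ic,
      class_index = class_index, context_index = context_index,
      n_events = n_events,
      generalize_superclasses = generalize_superclasses
    ),
    class = "context_stats"
  )
}

context_base_counts <- function(recipes, cls, known) {
  keys <- character(0)
  for (k in seq_len(nrow(recipes))) {
    members <- unique(recipes$ingredients[[k]]$ingredient_id)
    classes <- unname(cls[members])
    classes <- sort(unique(classes[!is.na(classes)]))
    if (length(classes) == 0) next
    keys <- c(keys, vapply(
      classes,
      function(i) paste(setdiff(classes, i), collapse = "|"),
      character(1)
    ))
  }
  c(table(keys))
}

#' @export
print.context_stats <- function(x, ...) {
  cat("<context_stats> ", length(x$class_index), " classes x ",
    length(x$context_index), " contexts, ", x$n_events, " events\n",
    sep = ""
  )
  invisible(x)
}

#' Positive pointwise mutual information of a class and a context
#'
#' Two normalisations are available. The default, `"max"`, evaluates
#' `max(0, log(F_ic * max(F_i, F_c) / (F_i * F_c)))`. The alternative,
#' `"total"`, is textbook PPMI with the corpus event count as normaliser:
#' `max(0, log(F_ic * N / (F_i * F_c)))` where `N` is the number of base
#' (class, context) counting events. An absent pair scores 0. The log base
#' (natural here) only rescales PPMI vectors and cancels in the cosine.
#'
#' @param stats A `context_stats` object.
#' @param i Class id.
#' @param c Context key (classes sorted and joined by `"|"`), e.g. the value
#'   of [context_key()].
#' @param normalizer `"max"` or `"total"`.
#' @return A nonnegative number.
#' @export
ppmi <- function(stats, i, c, normalizer = c("max", "total")) {
  normalizer <- match.arg(normalizer)
  if (!i %in% stats$class_index || !c %in% stats$context_index) {
    return(0)
  }
  f_ic <- stats$F_ic[i, c]
  if (f_ic == 0) {
    return(0)
  }
  f_i <- stats$F_i[[i]]
  f_c <- stats$F_c[[c]]
  z <- if (normalizer == "max") max(f_i, f_c) else stats$n_events
  max(0, log(f_ic * z / (f_i * f_c)))
}

#' Canonical context key for a set of class ids
#'
#' @param classes Character vector of class ids.
#' @return Sorted, duplicate-free key string joined by `"|"`.
#' @export
context_key <- function(classes) {
  paste(sort(unique(classes)), collapse = "|")
}

ppmi_vector <- function(stats, class_id, normalizer = "max") {
  v <- numeric(length(stats$context_index))
  if (!class_id %in% stats$class_index) {
    return(v)
  }
  row <- stats$F_ic[class_id, ]
  nz <- which(row > 0)
  if (length(nz) == 0) {
    return(v)
  }
  f_i <- stats$F_i[[class_id]]
  f_c <- stats$F_c[nz]
  z <- if (normalizer == "max") pmax(f_i, f_c) else stats$n_events
  v[nz] <- pmax(0, log(as.numeric(row[nz]) * z / (f_i * f_c)))
  v
}

#' Context substitutability score P
#'
#' Cosine similarity between the two ingredients' PPMI-weighted context
#' vectors over the canonical context index; 0 when either vector is all
#' zero. Ingredients linking to the same class receive identical vectors and
#' hence score 1 with each other. In \[0, 1\] because PPMI is nonnegative.
#'
#' @param stats A `context_stats` object.
#' @param a,b Ingredient ids (or class ids when `ingredients` is NULL).
#' @param ingredients Optional ingredient table for resolving class links.
#' @param normalizer Passed to the PPMI weighting; `"max"` or `"total"`.
#' @return A number in \[0, 1\].
#' @export
context_similarity <- function(stats, a, b, ingredients = NULL,
                               normalizer = "max") {
  resolve <- function(id) {
    cls <- if (is.null(ingredients)) id else ingredient_class(ingredients, id)
    if (is.na(cls)) {
      abort_lookup(paste0("ingredient '", id, "' has no class link"))
    }
    cls
  }
  cosine_similarity(
    ppmi_vector(stats, resolve(a), normalizer),
    ppmi_vector(stats, resolve(b), normalizer)
  )
}
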