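#' Construct a food-class ontology from an edge table
#'
#' The ontology is a poly-hierarchy (a DAG, not a tree) of food classes under
#' two relations: `subClassOf` (taxonomic specialisation) and `derivesFrom`
#' (a product derived from a source food, e.g. bacon deriving from pork).
#' Each relation's edge set must individually be acyclic.
#'
#' @param edges A data frame with columns `child`, `relation`, `parent`.
#'   `relation` must be `"subClassOf"` or `"derivesFrom"`.
#' @param labels Optional data frame with columns `class_id`, `label` giving
#'   display labels; classes without a row get their id as label.
#' @return An object of class `food_ontology`.
#' @export
#' @examples
#' ont <- ontology(tibble::tibble(
#'   child = c("russet potato", "potato"),
#'   relation = "subClassOf",
#'   parent = c("potato", "vegetable")
#' ))
#' class_ids(ont)
ontology <- function(edges = NULL, labels = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble::tibble(
      child = character(), relation = character(), parent = character()
    )
  }
  edges <- tibble::as_tibble(edges)[, c("child", "relation", "parent")]
  bad <- setdiff(unique(edges$relation), c("subClassOf", "derivesFrom"))
  if (length(bad) > 0) {
    abort_format(paste0("unknown relation token(s): ", paste(bad, collapse = ", ")))
  }
  classes <- sort(unique(c(edges$child, edges$parent)))
  if (!is.null(labels) && nrow(labels) > 0) {
    classes <- sort(unique(c(classes, labels$class_id)))
  }

  adj <- function(rel, from, to) {
    e <- edges[edges$relation == rel, ]
    split(e[[to]], factor(e[[from]], levels = classes))
  }
  ont <- structure(
    list(
      edges = edges,
      classes = classes,
      labels = label_map(classes, labels),
      up = list(
        subClassOf = adj("subClassOf", "child", "parent"),
        derivesFrom = adj("derivesFrom", "child", "parent")
      ),
      down = list(
        subClassOf = adj("subClassOf", "parent", "child"),
        derivesFrom = adj("derivesFrom", "parent", "child")
      )
    ),
    class = "food_ontology"
  )
  for (rel in c("subClassOf", "derivesFrom")) {
    member <- find_cycle_member(ont$up[[rel]], classes)
    if (!is.null(member)) {
      abort_validation(paste0(
        "cycle detected in ", rel, " edges involving class '", member, "'"
      ))
    }
  }
  ont
}

label_map <- function(classes, labels) {
  lab <- stats::setNames(classes, classes)
  if (!is.null(labels) && nrow(labels) > 0) {
    lab[labels$class_id] <- labels$label
  }
  lab
}

# Kahn's algorithm; returns one member of a cycle, or NULL if acyclic.
find_cycle_member <- function(up_adj, classes) {
  indeg <- stats::setNames(integer(length(classes)), classes)
  for (ps in up_adj) {
    for (p in ps) indeg[p] <- indeg[p] + 1L
  }
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0) {
    node <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (p in up_adj[[node]]) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen == length(classes)) NULL else names(indeg)[indeg > 0L][[1]]
}

#' @export
print.food_ontology <- function(x, ...) {
  cat("<food_ontology> ", length(x$classes), " classes, ",
    nrow(x$edges), " edges\n",
    sep = ""
  )
  invisible(x)
}

#' Read an ontology from a tab-separated edge list
#'
#' The file has a header row and columns `child`, `relation`, `parent`.
#' An empty file (or header only) yields an ontology with zero classes.
#'
#' @param path Path to the TSV file.
#' @return A `food_ontology`.
#' @export
load_ontology <- function(path) {
  edges <- read_tsv_quiet(path, c(
    child = "c", relation = "c", parent = "c"
  ))
  ontology(edges)
}

#' Write an ontology edge list to TSV
#'
#' @param ont A `food_ontology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ont, path) {
  readr::write_tsv(ont$edges, path)
  invisible(path)
}

read_tsv_quiet <- function(path, cols) {
  if (!file.exists(path)) abort_format(paste0("no such file: ", path))
  if (file.size(path) == 0) {
    out <- lapply(cols, function(t) if (t == "d") numeric() else character())
    return(tibble::as_tibble(out))
  }
  tb <- readr::read_tsv(
    path,
    col_types = paste(unname(cols), collapse = ""),
    progress = FALSE, show_col_types = FALSE
  )
  missing <- setdiff(names(cols), names(tb))
  if (length(missing) > 0) {
    abort_format(paste0(
      path, ": missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  tb[, names(cols)]
}

#' All class identifiers of an ontology
#'
#' @param ont A `food_ontology`.
#' @return Character vector of class ids.
#' @export
class_ids <- function(ont) {
  ont$classes
}

check_class <- function(ont, class_id) {
  if (!class_id %in% ont$classes) {
    abort_lookup(paste0("unknown class id: '", class_id, "'"))
  }
}

closure <- function(adj_by_rel, start, relations) {
  out <- character()
  frontier <- start
  seen <- stats::setNames(TRUE, start)
  while (length(frontier) > 0) {
    nxt <- unique(unlist(
      lapply(relations, function(rel) {
        unlist(adj_by_rel[[rel]][frontier], use.names = FALSE)
      }),
      use.names = FALSE
    ))
    nxt <- nxt[!(nxt %in% names(seen))]
    if (length(nxt) == 0) break
    seen[nxt] <- TRUE
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Transitive ancestors of a class
#'
#' Transitive closure upward over the selected relations, excluding the class
#' itself. Restriction checks traverse both `subClassOf` and `derivesFrom`;
#' the substitution-candidate hierarchy filter and the co-occurrence subclass
#' expansion use `subClassOf` only, so the relation set is an explicit
#' argument.
#'
#' @param ont A `food_ontology`.
#' @param class_id A class id present in the ontology.
#' @param relations Character vector of relation tokens to traverse.
#' @return Character vector of ancestor class ids (possibly empty).
#' @export
ancestors <- function(ont, class_id, relations = "subClassOf") {
  check_class(ont, class_id)
  sort(closure(ont$up, class_id, relations))
}

#' Transitive descendants of a class
#'
#' Mirror of [ancestors()] on reversed edges.
#'
#' @inheritParams ancestors
#' @return Character vector of descendant class ids (possibly empty).
#' @export
descendants <- function(ont, class_id, relations = "subClassOf") {
  check_class(ont, class_id)
  sort(closure(ont$down, class_id, relations))
}

#' Are two classes on one `subClassOf` path?
#'
#' TRUE iff `a` equals `b` or is an ancestor or descendant of `b` under
#' `subClassOf`. This is the relation used to filter substitution candidates
#' that are super- or subclasses of the target: a specific variety is not a
#' substitute for its own general class. Symmetric and reflexive.
#'
#' @param ont A `food_ontology`.
#' @param a,b Class ids.
#' @return Logical scalar.
#' @export
hierarchy_related <- function(ont, a, b) {
  check_class(ont, a)
  check_class(ont, b)
  a == b ||
    a %in% closure(ont$up, b, "subClassOf") ||
    a %in% closure(ont$down, b, "subClassOf")
}
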