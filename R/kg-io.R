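#' Read the ingredient table
#'
#' TSV with header and columns `ingredient_id`, `name`, `class_id`,
#' `nutrition_id`. Empty `class_id` / `nutrition_id` cells mean the
#' ingredient has no ontology link or no nutrition record. Names are
#' normalised (lowercased, trimmed, whitespace collapsed) into a `name`
#' column used for all joins; the original spelling is kept in `raw_name`.
#' Each ingredient may carry at most one class link; duplicated ids are
#' rejected rather than silently merged.
#'
#' @param path Path to the TSV file.
#' @param ont Optional `food_ontology`; when given, class links are checked.
#' @return A tibble with columns `ingredient_id`, `name`, `raw_name`,
#'   `class_id`, `nutrition_id`.
#' @export
load_ingredients <- function(path, ont = NULL) {
  tb <- read_tsv_quiet(path, c(
    ingredient_id = "c", name = "c", class_id = "c", nutrition_id = "c"
  ))
  ingredients_table(tb, ont)
}

ingredients_table <- function(tb, ont = NULL) {
  tb <- tibble::as_tibble(tb)
  dup <- tb$ingredient_id[duplicated(tb$ingredient_id)]
  if (length(dup) > 0) {
    abort_validation(paste0(
      "duplicate ingredient id(s): ", paste(unique(dup), collapse = ", "),
      " (at most one class link per ingredient)"
    ))
  }
  out <- tibble::tibble(
    ingredient_id = tb$ingredient_id,
    name = normalize_name(tb$name),
    raw_name = tb$name,
    class_id = dplyr::na_if(tb$class_id, ""),
    nutrition_id = dplyr::na_if(tb$nutrition_id, "")
  )
  if (!is.null(ont)) {
    bad <- setdiff(stats::na.omit(out$class_id), class_ids(ont))
    if (length(bad) > 0) {
      abort_validation(paste0(
        "ingredient class link(s) not in ontology: ",
        paste(bad, collapse = ", ")
      ))
    }
  }
  out
}

#' Write the ingredient table to TSV
#'
#' @param ingredients Tibble as returned by [load_ingredients()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ingredients <- function(ingredients, path) {
  out <- tibble::tibble(
    ingredient_id = ingredients$ingredient_id,
    name = ingredients$raw_name,
    class_id = dplyr::coalesce(ingredients$class_id, ""),
    nutrition_id = dplyr::coalesce(ingredients$nutrition_id, "")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a recipe corpus from JSON lines
#'
#' One JSON object per line with fields `recipe_id`, `name`, `ingredients`
#' (array of objects with `ingredient_id`, optional `amount`, optional
#' `unit`), optional `servings` and optional `instructions`. An absent
#' amount (a "--" quantity) is kept as `NA` and contributes zero to
#' nutrition totals.
#'
#' @param path Path to the JSONL file.
#' @param ingredients Optional ingredient table; when given, every recipe
#'   ingredient id must resolve against it.
#' @return A tibble with columns `recipe_id`, `name`, `servings`,
#'   `instructions` and a list-column `ingredients` of tibbles
#'   (`ingredient_id`, `amount`, `unit`).
#' @export
load_recipes <- function(path, ingredients = NULL) {
  if (!file.exists(path)) abort_format(paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = FALSE))
  recipes_table(recs, ingredients)
}

recipes_table <- function(recs, ingredients = NULL) {
  parse_one <- function(r) {
    ing <- purrr::map_dfr(r$ingredients, function(qi) {
      tibble::tibble(
        ingredient_id = qi$ingredient_id,
        amount = if (is.null(qi$amount)) NA_real_ else as.numeric(qi$amount),
        unit = if (is.null(qi$unit)) "" else as.character(qi$unit)
      )
    })
    if (nrow(ing) == 0) {
      abort_validation(paste0("recipe '", r$recipe_id, "' has no ingredients"))
    }
    if (any(!is.na(ing$amount) & ing$amount < 0)) {
      abort_validation(paste0("recipe '", r$recipe_id, "' has a negative amount"))
    }
    tibble::tibble(
      recipe_id = r$recipe_id,
      name = r$name %||% r$recipe_id,
      servings = if (is.null(r$servings)) NA_integer_ else as.integer(r$servings),
      instructions = if (is.null(r$instructions)) "" else as.character(r$instructions),
      ingredients = list(ing)
    )
  }
  out <- purrr::map_dfr(recs, parse_one)
  if (!is.null(ingredients)) {
    for (k in seq_len(nrow(out))) {
      bad <- setdiff(out$ingredients[[k]]$ingredient_id, ingredients$ingredient_id)
      if (length(bad) > 0) {
        abort_validation(paste0(
          "recipe '", out$recipe_id[[k]], "' references unknown ingredient(s): ",
          paste(bad, collapse = ", ")
        ))
      }
    }
  }
  out
}

#' Write a recipe corpus to JSON lines
#'
#' @param recipes Recipe tibble as returned by [load_recipes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recipes <- function(recipes, path) {
  lines <- purrr::map_chr(seq_len(nrow(recipes)), function(k) {
    ing <- recipes$ingredients[[k]]
    obj <- list(
      recipe_id = recipes$recipe_id[[k]],
      name = recipes$name[[k]],
      ingredients = purrr::map(seq_len(nrow(ing)), function(j) {
        qi <- list(ingredient_id = ing$ingredient_id[[j]])
        if (!is.na(ing$amount[[j]])) qi$amount <- ing$amount[[j]]
        if (nzchar(ing$unit[[j]])) qi$unit <- ing$unit[[j]]
        qi
      })
    )
    if (!is.na(recipes$servings[[k]])) obj$servings <- recipes$servings[[k]]
    if (nzchar(recipes$instructions[[k]])) obj$instructions <- recipes$instructions[[k]]
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read nutrition records
#'
#' `nutrition.tsv` is long-format per-100 g data: columns `nutrition_id`,
#' `nutrient`, `amount`, `unit`. The companion `common_units.tsv` lists the
#' textual measure descriptions and their gram weights (`nutrition_id`,
#' `description`, `grams`), in file order -- the first row for a record is
#' the default weight used when a recipe unit cannot be matched.
#'
#' @param path Path to `nutrition.tsv`.
#' @param common_units_path Path to `common_units.tsv`.
#' @return A list of class `nutrition_table` with tibbles `per_100g` and
#'   `common_units`.
#' @export
load_nutrition <- function(path, common_units_path) {
  per_100g <- read_tsv_quiet(path, c(
    nutrition_id = "c", nutrient = "c", amount = "d", unit = "c"
  ))
  if (any(per_100g$amount < 0)) {
    abort_validation("per-100 g nutrient amounts must be nonnegative")
  }
  common_units <- read_tsv_quiet(common_units_path, c(
    nutrition_id = "c", description = "c", grams = "d"
  ))
  if (any(common_units$grams <= 0)) {
    abort_validation("common-unit gram weights must be positive")
  }
  nutrition_table(per_100g, common_units)
}

nutrition_table <- function(per_100g, common_units) {
  structure(
    list(
      per_100g = tibble::as_tibble(per_100g),
      common_units = tibble::as_tibble(common_units)
    ),
    class = "nutrition_table"
  )
}

#' @export
print.nutrition_table <- function(x, ...) {
  cat("<nutrition_table> ", length(unique(x$per_100g$nutrition_id)),
    " records, ", length(unique(x$per_100g$nutrient)), " nutrients\n",
    sep = ""
  )
  invisible(x)
}

#' Write nutrition records to TSV
#'
#' @param nutrition A `nutrition_table`.
#' @param path Path for `nutrition.tsv`.
#' @param common_units_path Path for `common_units.tsv`.
#' @return `path`, invisibly.
#' @export
write_nutrition <- function(nutrition, path, common_units_path) {
  readr::write_tsv(nutrition$per_100g, path)
  readr::write_tsv(nutrition$common_units, common_units_path)
  invisible(path)
}

#' Read ground-truth substitution pairs
#'
#' TSV with header and columns `target_id`, `substitute_id`; one directed
#' pair per line. Substitutions are one-to-one (a single ingredient replaces
#' another) and directed: a pair (a, b) does not imply (b, a). The candidate
#' pool is the set of unique ingredient ids appearing anywhere in the file,
#' mirroring evaluation against only the ingredients a dataset mentions.
#'
#' @param path Path to the TSV file.
#' @return A list of class `ground_truth` with `pairs` (tibble `target_id`,
#'   `substitute_id`) and `candidate_pool` (character vector).
#' @export
load_ground_truth <- function(path) {
  tb <- read_tsv_quiet(path, c(target_id = "c", substitute_id = "c"))
  ground_truth(tb)
}

#' Construct a ground-truth set from a pair table
#'
#' @param pairs Data frame with columns `target_id`, `substitute_id`.
#' @param candidate_pool Optional explicit candidate pool; defaults to the
#'   unique ids appearing in `pairs`.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(pairs, candidate_pool = NULL) {
  pairs <- tibble::tibble(
    target_id = as.character(pairs$target_id),
    substitute_id = as.character(pairs$substitute_id)
  )
  if (any(pairs$target_id == pairs$substitute_id)) {
    abort_validation("a ground-truth pair may not map an ingredient to itself")
  }
  pairs <- dplyr::distinct(pairs)
  pool <- candidate_pool %||%
    sort(unique(c(pairs$target_id, pairs$substitute_id)))
  structure(
    list(pairs = pairs, candidate_pool = pool),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", nrow(x$pairs), " pairs, ",
    length(unique(x$pairs$target_id)), " targets, pool of ",
    length(x$candidate_pool), " ingredients\n",
    sep = ""
  )
  invisible(x)
}

#' Write ground-truth pairs to TSV
#'
#' @param truth A `ground_truth` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_tsv(truth$pairs, path)
  invisible(path)
}

#' Load a complete food knowledge graph from a directory
#'
#' Expects `ontology.tsv`, `ingredients.tsv`, `recipes.jsonl`,
#' `nutrition.tsv` and `common_units.tsv`, plus optional `truth.tsv` and
#' `reviews.txt`, as written by [write_food_kg()] or the fixture generator.
#'
#' @param dir Directory containing the files.
#' @return A list of class `food_kg` with elements `ontology`,
#'   `ingredients`, `recipes`, `nutrition`, and (when present) `truth` and
#'   `reviews`.
#' @export
load_food_kg <- function(dir) {
  ont <- load_ontology(file.path(dir, "ontology.tsv"))
  ingredients <- load_ingredients(file.path(dir, "ingredients.tsv"), ont)
  recipes <- load_recipes(file.path(dir, "recipes.jsonl"), ingredients)
  nutrition <- load_nutrition(
    file.path(dir, "nutrition.tsv"),
    file.path(dir, "common_units.tsv")
  )
  kg <- list(
    ontology = ont, ingredients = ingredients,
    recipes = recipes, nutrition = nutrition
  )
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path)) kg$truth <- load_ground_truth(truth_path)
  reviews_path <- file.path(dir, "reviews.txt")
  if (file.exists(reviews_path)) {
    kg$reviews <- readLines(reviews_path, encoding = "UTF-8")
  }
  structure(kg, class = "food_kg")
}

#' Write a food knowledge graph to a directory
#'
#' @param kg A `food_kg` bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_food_kg <- function(kg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ontology(kg$ontology, file.path(dir, "ontology.tsv"))
  write_ingredients(kg$ingredients, file.path(dir, "ingredients.tsv"))
  write_recipes(kg$recipes, file.path(dir, "recipes.jsonl"))
  write_nutrition(
    kg$nutrition,
    file.path(dir, "nutrition.tsv"),
    file.path(dir, "common_units.tsv")
  )
  if (!is.null(kg$truth)) {
    write_ground_truth(kg$truth, file.path(dir, "truth.tsv"))
  }
  if (!is.null(kg$reviews)) {
    writeLines(kg$reviews, file.path(dir, "reviews.txt"), useBytes = TRUE)
  }
  invisible(dir)
}

#' @export
print.food_kg <- function(x, ...) {
  cat("<food_kg>\n")
  cat("  classes:     ", length(class_ids(x$ontology)), "\n", sep = "")
  cat("  ingredients: ", nrow(x$ingredients), "\n", sep = "")
  cat("  recipes:     ", nrow(x$recipes), "\n", sep = "")
  if (!is.null(x$truth)) {
    cat("  truth pairs: ", nrow(x$truth$pairs), "\n", sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ingredient_class <- function(ingredients, ingredient_id) {
  k <- match(ingredient_id, ingredients$ingredient_id)
  if (anyNA(k)) {
    abort_lookup(paste0(
      "unknown ingredient id(s): ",
      paste(ingredient_id[is.na(k)], collapse = ", ")
    ))
  }
  ingredients$class_id[k]
}
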