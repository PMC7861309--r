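#' Define a dietary profile
#'
#' A profile carries the two kinds of constraint the suggestion engine
#' understands: food classes whose members (and anything below or deriving
#' from them) must not be eaten, and nutrients whose intake should be
#' reduced, optionally with hard per-serving limits.
#'
#' @param prohibited_classes Character vector of prohibited class ids.
#' @param reduce_nutrients Character vector of nutrient names to reduce, in
#'   priority order.
#' @param nutrient_limits Optional named numeric vector of per-serving
#'   maxima (same units as the nutrition table).
#' @return A `dietary_profile`.
#' @export
dietary_profile <- function(prohibited_classes = character(),
                            reduce_nutrients = character(),
                            nutrient_limits = NULL) {
  if (length(reduce_nutrients) > 0 && any(!nzchar(reduce_nutrients))) {
    abort_parameter("nutrient names must be nonempty")
  }
  if (!is.null(nutrient_limits) && any(nutrient_limits <= 0)) {
    abort_parameter("nutrient limits must be positive")
  }
  structure(
    list(
      prohibited_classes = prohibited_classes,
      reduce_nutrients = reduce_nutrients,
      nutrient_limits = nutrient_limits
    ),
    class = "dietary_profile"
  )
}

#' Convert a quantified recipe ingredient to grams
#'
#' Resolution order: (1) recognised mass units (g, kg, mg, oz, lb) convert
#' directly; (2) otherwise the unit text is substring-matched,
#' case-insensitively, against the record's common-unit descriptions and the
#' first match supplies the gram weight; (3) with no match (or an empty
#' unit, as in "2 lemons"), the first common unit is the default weight.
#' Volume units without a matching description are not density-converted --
#' they fall through to the default like any other unmatched unit. An absent
#' amount contributes zero.
#'
#' @param amount Numeric amount (NA for an unquantified "--" row).
#' @param unit Unit text (may be empty).
#' @param record One record's common units: tibble with `description`,
#'   `grams` in file order (e.g. the rows of `nutrition$common_units` for
#'   one `nutrition_id`).
#' @return Grams as a single nonnegative number.
#' @export
#' @examples
#' to_grams(1, "kg", tibble::tibble(description = character(), grams = numeric()))
to_grams <- function(amount, unit, record) {
  if (is.na(amount)) {
    return(0)
  }
  unit_norm <- normalize_name(unit)
  mass <- c(g = 1, gram = 1, grams = 1, kg = 1000, mg = 0.001,
            oz = 28.3495, ounce = 28.3495, ounces = 28.3495,
            lb = 453.592, lbs = 453.592, pound = 453.592, pounds = 453.592)
  if (unit_norm %in% names(mass)) {
    return(amount * mass[[unit_norm]])
  }
  if (is.null(record) || nrow(record) == 0) {
    abort_validation(paste0(
      "cannot convert unit '", unit, "': no common units and not a mass unit"
    ))
  }
  if (nzchar(unit_norm)) {
    hit <- which(stringr::str_detect(
      normalize_name(record$description),
      stringr::fixed(unit_norm)
    ))
    if (length(hit) > 0) {
      return(amount * record$grams[[hit[[1]]]])
    }
  }
  amount * record$grams[[1]]
}

common_units_for <- function(nutrition, nutrition_id) {
  nutrition$common_units[
    nutrition$common_units$nutrition_id == nutrition_id, ,
    drop = FALSE
  ]
}

#' Nutrition breakdown of a recipe
#'
#' Converts each quantified ingredient to grams, scales the per-100 g
#' nutrient amounts, and totals them. Unquantified ("--") rows contribute
#' zero. When the recipe declares servings, per-serving totals are included.
#'
#' @param recipe One row of a recipe tibble (or a list with the same
#'   fields).
#' @param nutrition A `nutrition_table`.
#' @param ingredients Ingredient table linking ingredients to nutrition
#'   records.
#' @return A `nutrient_breakdown`: `per_ingredient` (tibble `ingredient_id`,
#'   `grams`, `nutrient`, `amount`), `recipe_totals` and optionally
#'   `per_serving` (named numeric vectors).
#' @export
recipe_nutrients <- function(recipe, nutrition, ingredients) {
  if (is.data.frame(recipe)) {
    stopifnot(nrow(recipe) == 1)
    recipe <- as.list(recipe)
    recipe$ingredients <- recipe$ingredients[[1]]
  }
  qi <- recipe$ingredients
  nid_of <- stats::setNames(ingredients$nutrition_id, ingredients$ingredient_id)
  rows <- purrr::map_dfr(seq_len(nrow(qi)), function(k) {
    id <- qi$ingredient_id[[k]]
    nid <- nid_of[[id]]
    quantified <- !is.na(qi$amount[[k]])
    if (is.na(nid)) {
      if (quantified) {
        abort_validation(paste0(
          "quantified ingredient '", id, "' has no nutrition record"
        ))
      }
      return(tibble::tibble(
        ingredient_id = id, grams = 0,
        nutrient = character(), amount = numeric()
      )[0, ])
    }
    grams <- to_grams(
      qi$amount[[k]], qi$unit[[k]],
      common_units_for(nutrition, nid)
    )
    per <- nutrition$per_100g[nutrition$per_100g$nutrition_id == nid, ]
    tibble::tibble(
      ingredient_id = id,
      grams = grams,
      nutrient = per$nutrient,
      amount = grams / 100 * per$amount
    )
  })
  totals <- tapply(rows$amount, rows$nutrient, sum)
  totals <- stats::setNames(as.numeric(totals), names(totals))
  out <- list(
    recipe_id = recipe$recipe_id,
    per_ingredient = rows,
    recipe_totals = totals
  )
  servings <- recipe$servings
  if (!is.null(servings) && !is.na(servings)) {
    out$per_serving <- totals / servings
  }
  structure(out, class = "nutrient_breakdown")
}

#' @export
print.nutrient_breakdown <- function(x, digits = 1, ...) {
  cat("<nutrient_breakdown> recipe '", x$recipe_id, "'\n", sep = "")
  for (n in names(x$recipe_totals)) {
    cat("  ", n, ": ", round(x$recipe_totals[[n]], digits), "\n", sep = "")
  }
  invisible(x)
}

#' Does an ingredient violate a dietary restriction?
#'
#' TRUE iff the ingredient's class equals, or reaches via `subClassOf` /
#' `derivesFrom` ancestor paths, any prohibited class. Both relations
#' participate: a product derived from a prohibited food (bacon deriving
#' from pork) is itself prohibited. Unlinked ingredients are treated as
#' non-violating.
#'
#' @param ingredient_id Ingredient id.
#' @param profile A `dietary_profile`.
#' @param ont A `food_ontology`.
#' @param ingredients Ingredient table with class links.
#' @return Logical scalar.
#' @export
violates_restriction <- function(ingredient_id, profile, ont, ingredients) {
  bad <- setdiff(profile$prohibited_classes, class_ids(ont))
  if (length(bad) > 0) {
    abort_parameter(paste0(
      "prohibited class(es) not in ontology: ", paste(bad, collapse = ", ")
    ))
  }
  cls <- ingredient_class(ingredients, ingredient_id)
  if (is.na(cls)) {
    return(FALSE)
  }
  reach <- c(cls, ancestors(ont, cls, c("subClassOf", "derivesFrom")))
  any(reach %in% profile$prohibited_classes)
}

#' Ingredients contributing most to a nutrient
#'
#' @param breakdown A `nutrient_breakdown`.
#' @param nutrient Nutrient name present in the breakdown.
#' @return Tibble with `ingredient_id`, `amount`, descending by contributed
#'   amount, ties broken by id.
#' @export
top_contributors <- function(breakdown, nutrient) {
  if (!nutrient %in% names(breakdown$recipe_totals)) {
    abort_lookup(paste0("nutrient '", nutrient, "' not in breakdown"))
  }
  rows <- breakdown$per_ingredient
  rows <- rows[rows$nutrient == nutrient, c("ingredient_id", "amount")]
  missing <- setdiff(unique(breakdown$per_ingredient$ingredient_id),
                     rows$ingredient_id)
  if (length(missing) > 0) {
    rows <- dplyr::bind_rows(
      rows, tibble::tibble(ingredient_id = missing, amount = 0)
    )
  }
  rows[order(-rows$amount, rows$ingredient_id), ]
}

#' Keep only "healthy" substitution candidates
#'
#' A healthy candidate contains strictly less of the limited nutrient per
#' 100 g than the target and violates no class restriction in the profile.
#' Candidates without a nutrition record are dropped; a target without one
#' is an error.
#'
#' @param target Target ingredient id.
#' @param candidates Character vector of candidate ids.
#' @param nutrient Nutrient being reduced.
#' @param nutrition A `nutrition_table`.
#' @param profile A `dietary_profile`.
#' @param ont A `food_ontology`.
#' @param ingredients Ingredient table.
#' @return Character vector of surviving candidate ids.
#' @export
healthy_candidates <- function(target, candidates, nutrient, nutrition,
                               profile, ont, ingredients) {
  per_100g_of <- function(id) {
    nid <- ingredients$nutrition_id[[match(id, ingredients$ingredient_id)]]
    if (is.na(nid)) {
      return(NA_real_)
    }
    per <- nutrition$per_100g
    hit <- per$amount[per$nutrition_id == nid & per$nutrient == nutrient]
    if (length(hit) == 0) NA_real_ else hit[[1]]
  }
  target_amt <- per_100g_of(target)
  if (is.na(target_amt)) {
    abort_validation(paste0(
      "target '", target, "' lacks a '", nutrient, "' nutrition record"
    ))
  }
  keep <- vapply(candidates, function(cand) {
    amt <- per_100g_of(cand)
    !is.na(amt) && amt < target_amt &&
      !violates_restriction(cand, profile, ont, ingredients)
  }, logical(1))
  candidates[keep]
}

#' Suggest constraint-satisfying substitutions for a recipe
#'
#' Flags, per reduce-nutrient in the profile, the ingredient contributing
#' most to that nutrient, plus every ingredient violating a class
#' restriction; for each flagged ingredient it ranks the healthy candidates
#' (strictly lower in the nutrient, no restriction violation, not a
#' super/subclass of the target) by DIISH score.
#'
#' @param recipe One recipe row.
#' @param profile A `dietary_profile`.
#' @param kg A `food_kg` bundle.
#' @param score_provider Component-score provider.
#' @param spec A `diish_spec`.
#' @param candidates Candidate pool; defaults to all ingredients in the
#'   knowledge graph.
#' @param top Number of ranked substitutes to keep per flagged ingredient.
#' @return A tibble of class `substitution_report` with one row per flagged
#'   ingredient: `ingredient_id`, `reason` (`"nutrient:<name>"` or
#'   `"restriction"`), and a list-column `substitutes` of `ranked_list`s.
#' @export
suggest_substitutions <- function(recipe, profile, kg, score_provider,
                                  spec = default_diish_spec(),
                                  candidates = NULL, top = 5) {
  candidates <- candidates %||% kg$ingredients$ingredient_id
  if (is.data.frame(recipe)) {
    stopifnot(nrow(recipe) == 1)
    recipe <- as.list(recipe)
    recipe$ingredients <- recipe$ingredients[[1]]
  }
  member_ids <- unique(recipe$ingredients$ingredient_id)

  flagged <- tibble::tibble(ingredient_id = character(), reason = character())
  if (length(profile$reduce_nutrients) > 0) {
    breakdown <- recipe_nutrients(recipe, kg$nutrition, kg$ingredients)
    for (nutrient in profile$reduce_nutrients) {
      if (!nutrient %in% names(breakdown$recipe_totals)) next
      tc <- top_contributors(breakdown, nutrient)
      if (nrow(tc) > 0 && tc$amount[[1]] > 0) {
        flagged <- dplyr::bind_rows(flagged, tibble::tibble(
          ingredient_id = tc$ingredient_id[[1]],
          reason = paste0("nutrient:", nutrient)
        ))
      }
    }
  }
  violators <- member_ids[vapply(
    member_ids, violates_restriction, logical(1),
    profile = profile, ont = kg$ontology, ingredients = kg$ingredients
  )]
  if (length(violators) > 0) {
    flagged <- dplyr::bind_rows(flagged, tibble::tibble(
      ingredient_id = violators, reason = "restriction"
    ))
  }
  flagged <- dplyr::distinct(flagged)

  flagged$substitutes <- purrr::map2(
    flagged$ingredient_id, flagged$reason,
    function(id, reason) {
      pool <- setdiff(candidates, member_ids)
      if (startsWith(reason, "nutrient:")) {
        pool <- healthy_candidates(
          id, pool, sub("^nutrient:", "", reason),
          kg$nutrition, profile, kg$ontology, kg$ingredients
        )
      } else {
        pool <- pool[!vapply(
          pool, violates_restriction, logical(1),
          profile = profile, ont = kg$ontology, ingredients = kg$ingredients
        )]
      }
      ranked <- rank_substitutes(
        id, pool, score_provider, spec,
        ont = kg$ontology, ingredients = kg$ingredients
      )
      utils::head(ranked, top)
    }
  )
  structure(flagged, class = c("substitution_report", class(flagged)))
}
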