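# Shared builders for hand-sized knowledge graphs, plus a lazily built
# default fixture reused by the heavier end-to-end tests.

ont_from_edges <- function(child, parent, relation = "subClassOf") {
  ontology(tibble::tibble(child = child, relation = relation, parent = parent))
}

write_tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# random parent-pointing DAG: node k (k > 1) picks parents among 1..k-1
random_dag_edges <- function(n_nodes, seed) {
  withr::with_seed(seed, {
    nodes <- paste0("c", seq_len(n_nodes))
    rows <- purrr::map_dfr(2:n_nodes, function(k) {
      n_par <- sample(1:min(2, k - 1), 1)
      tibble::tibble(
        child = nodes[[k]],
        relation = "subClassOf",
        parent = sample(nodes[seq_len(k - 1)], n_par)
      )
    })
    rows
  })
}

igraph_reachable <- function(edges, from, mode) {
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")],
    directed = TRUE
  )
  if (!from %in% igraph::V(g)$name) {
    return(character(0))
  }
  out <- igraph::subcomponent(g, from, mode = mode)$name
  setdiff(out, from)
}

# A small diet-test knowledge graph for the roasted-potato worked example:
# fixed gram quantities and per-100 g carbohydrate values.
roast_potato_kg <- function() {
  ont <- ont_from_edges(
    child = c(
      "potato class", "lemon class", "red onion class", "olive oil class",
      "pepper class", "salt class", "turnip class", "cauliflower class",
      "squash class"
    ),
    parent = c(
      "vegetable", "fruit", "vegetable", "fat", "spice", "spice",
      "vegetable", "vegetable", "vegetable"
    )
  )
  ing <- ingredients_table(tibble::tibble(
    ingredient_id = c(
      "potatoes", "lemon", "red onion", "olive oil", "black pepper",
      "coarse sea salt", "turnip", "cauliflower", "squash"
    ),
    name = c(
      "Potatoes", "Lemon", "Red Onion", "Olive Oil", "Black Pepper",
      "Coarse Sea Salt", "Turnip", "Cauliflower", "Squash"
    ),
    class_id = c(
      "potato class", "lemon class", "red onion class", "olive oil class",
      "pepper class", "salt class", "turnip class", "cauliflower class",
      "squash class"
    ),
    nutrition_id = c(
      "n_pot", "n_lem", "n_oni", "n_oil", "n_pep", "n_salt",
      "n_tur", "n_cau", "n_squ"
    )
  ), ont)
  carbs <- c(
    n_pot = 17.5, n_lem = 9.3, n_oni = 9.3, n_oil = 0, n_pep = 0,
    n_salt = 0, n_tur = 6.4, n_cau = 5.0, n_squ = 6.9
  )
  per <- purrr::map_dfr(names(carbs), function(nid) {
    tibble::tibble(
      nutrition_id = nid, nutrient = "carbohydrate",
      amount = carbs[[nid]], unit = "g"
    )
  })
  cu <- tibble::tibble(
    nutrition_id = c("n_lem", "n_oni", "n_oil", "n_oil",
                     "n_tur", "n_cau", "n_squ", "n_pot"),
    description = c("1 fruit", "1 onion", "1 tsp", "1 tbsp",
                    "1 cup", "1 cup", "1 cup", "1 cup"),
    grams = c(58, 160, 13 / 3, 13, 130, 107, 113, 150)
  )
  recipe <- recipes_table(list(list(
    recipe_id = "roast_potatoes",
    name = "lemon and red onion roasted potatoes",
    servings = 4,
    instructions = "roast everything",
    ingredients = list(
      list(ingredient_id = "black pepper"),
      list(ingredient_id = "coarse sea salt"),
      list(ingredient_id = "olive oil", amount = 6, unit = "tsp"),
      list(ingredient_id = "lemon", amount = 2, unit = ""),
      list(ingredient_id = "red onion", amount = 3, unit = ""),
      list(ingredient_id = "potatoes", amount = 1, unit = "kg")
    )
  )), ing)
  structure(
    list(
      ontology = ont, ingredients = ing, recipes = recipe,
      nutrition = nutrition_table(per, cu)
    ),
    class = "food_kg"
  )
}

# score provider with hand-settable component tables: a named list
# target -> tibble(candidate_id, W, S, D, P)
manual_provider <- function(tables) {
  function(target, candidates) {
    tb <- tables[[target]]
    if (is.null(tb)) {
      rlang::abort("unknown target", class = "substkg_lookup_error")
    }
    out <- tb[match(candidates, tb$candidate_id), ]
    out$candidate_id <- candidates
    out[is.na(out$W), c("W", "S", "D", "P")] <- 0
    out
  }
}

# lazy one-time default fixture + fitted components (shared across files)
.substkg_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.substkg_cache$kg)) {
    .substkg_cache$kg <- generate_food_kg(fixture_params(seed = 42))
  }
  .substkg_cache$kg
}

default_components <- function() {
  if (is.null(.substkg_cache$comp)) {
    .substkg_cache$comp <- fit_diish_components(default_fixture(), seed = 42)
  }
  .substkg_cache$comp
}
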