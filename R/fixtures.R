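#' Parameters for the synthetic food knowledge graph
#'
#' The generator plants the statistical structure the substitutability
#' scores assume in real data: families of interchangeable ingredients that
#' occupy the same slot in recipes (so family mates share recipe contexts
#' and co-occurrence company), sibling leaf classes per family in the
#' ontology (so truth pairs survive the hierarchy filter), and
#' family-correlated nutrient profiles with clearly separated high- and
#' low-carbohydrate families (so strict-inequality nutrient filtering has a
#' margin rather than a knife edge).
#'
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param n_families Number of substitutable ingredient families.
#' @param members_per_family Ingredients per family.
#' @param tree_depth Ontology depth from root to leaf classes (minimum 4).
#' @param n_recipes Number of recipes.
#' @param recipe_len Integer range (length 2) of family slots per recipe.
#' @param noise_rate Probability a recipe also draws pantry-staple noise
#'   ingredients.
#' @param high_carb_families Number of families designated high-carb.
#' @return A `fixture_params` list.
#' @export
fixture_params <- function(seed = 1, n_families = 8, members_per_family = 4,
                           tree_depth = 4, n_recipes = 400,
                           recipe_len = c(4, 8), noise_rate = 0.1,
                           high_carb_families = 3) {
  stopifnot(
    n_families >= 1, members_per_family >= 2, members_per_family <= 8,
    tree_depth >= 4,
    n_recipes >= 1, length(recipe_len) == 2, recipe_len[1] >= 1,
    recipe_len[2] >= recipe_len[1]
  )
  if (noise_rate < 0 || noise_rate > 1) {
    abort_parameter("noise_rate must lie in [0, 1]")
  }
  if (high_carb_families > n_families) {
    abort_parameter("high_carb_families cannot exceed n_families")
  }
  structure(
    list(
      seed = seed, n_families = n_families,
      members_per_family = members_per_family, tree_depth = tree_depth,
      n_recipes = n_recipes, recipe_len = recipe_len,
      noise_rate = noise_rate, high_carb_families = high_carb_families
    ),
    class = "fixture_params"
  )
}

family_stems <- c(
  "tuber", "gourd", "leafgreen", "bean", "grain", "cheese",
  "fishcut", "berry", "fatoil", "herbleaf", "rootveg", "nutseed",
  "fowlcut", "noodle", "brine", "cultur"
)
member_suffixes <- c(
  "one", "two", "three", "four", "five", "six", "seven", "eight"
)
staple_names <- c("salt", "oliveoil", "pepperspice", "water")
cooking_verbs <- c(
  "mix", "bake", "stir", "roast", "simmer", "chop", "serve", "heat",
  "whisk", "season"
)
distractor_lines <- c(
  "great recipe, made as written",
  "my family loved it and asked for seconds",
  "will make again soon",
  "a bit too salty for us but still nice",
  "came out perfect on the first try",
  "doubled the batch for a party",
  "the timing in the directions was spot on",
  "lovely weeknight dinner idea"
)

#' Generate a synthetic food knowledge graph
#'
#' Builds the complete fixture bundle: ontology, ingredient table, recipe
#' corpus, nutrition records with common units, within-family ground-truth
#' substitution pairs, review lines embedding those pairs in substitution
#' phrasings (plus distractor lines), and a synthetic "general language"
#' vector table with family-correlated token vectors that stands in for a
#' pretrained embedding provider. Fully deterministic for a fixed seed.
#'
#' @param params A `fixture_params`.
#' @return A `food_kg` bundle with additional elements `general_vectors`
#'   (an `embedding_model`) and `manifest` (the generation parameters).
#' @export
generate_food_kg <- function(params = fixture_params()) {
  stopifnot(inherits(params, "fixture_params"))
  withr::with_seed(params$seed, generate_food_kg_impl(params))
}

generate_food_kg_impl <- function(params) {
  nf <- params$n_families
  stems <- rep_len(family_stems, nf)
  stems <- ifelse(
    duplicated(stems),
    paste0(stems, cumsum(duplicated(stems))), stems
  )

  # --- ontology -------------------------------------------------------
  branches <- c("plantfood", "animalfood")
  edges <- tibble::tibble(
    child = branches, relation = "subClassOf", parent = "food"
  )
  n_mid <- params$tree_depth - 4L
  fam_class <- paste0("class_", stems)
  for (f in seq_len(nf)) {
    parent <- branches[[(f - 1) %% 2 + 1]]
    if (n_mid > 0) {
      mids <- paste0("group_", stems[[f]], "_", seq_len(n_mid))
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        child = c(mids[1], mids[-1]),
        relation = "subClassOf",
        parent = c(parent, mids[-n_mid])
      )[seq_len(n_mid), ])
      parent <- mids[[n_mid]]
    }
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      child = fam_class[[f]], relation = "subClassOf", parent = parent
    ))
  }
  members <- purrr::map(seq_len(nf), function(f) {
    paste0(stems[[f]], member_suffixes[seq_len(params$members_per_family)])
  })
  for (f in seq_len(nf)) {
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      child = paste0("class_", members[[f]]),
      relation = "subClassOf",
      parent = fam_class[[f]]
    ))
  }
  # derivesFrom chains for the first two families (restriction checks)
  n_src <- min(2L, nf)
  src_class <- paste0("source_", stems[seq_len(n_src)])
  edges <- dplyr::bind_rows(
    edges,
    tibble::tibble(child = src_class, relation = "subClassOf", parent = "food"),
    tibble::tibble(
      child = fam_class[seq_len(n_src)], relation = "derivesFrom",
      parent = src_class
    )
  )
  staple_class <- paste0("class_", staple_names)
  edges <- dplyr::bind_rows(
    edges,
    tibble::tibble(child = "staple", relation = "subClassOf", parent = "food"),
    tibble::tibble(child = staple_class, relation = "subClassOf", parent = "staple")
  )
  ont <- ontology(edges)

  # --- ingredients (one per leaf class; one shared-class extra) -------
  shared_extra <- paste0(members[[1]][[1]], "bis")
  ing_names <- c(unlist(members), shared_extra, staple_names)
  ing_class <- c(
    paste0("class_", unlist(members)),
    paste0("class_", members[[1]][[1]]),
    staple_class
  )
  ingredients <- ingredients_table(tibble::tibble(
    ingredient_id = ing_names,
    name = ing_names,
    class_id = ing_class,
    nutrition_id = paste0("nutr_", ing_names)
  ), ont)

  family_of <- stats::setNames(
    rep(seq_len(nf), lengths(members)), unlist(members)
  )
  family_of[shared_extra] <- 1L
  draw_pools <- purrr::map(seq_len(nf), function(f) {
    if (f == 1) c(members[[f]], shared_extra) else members[[f]]
  })

  # --- nutrition ------------------------------------------------------
  carb_mean <- ifelse(
    seq_len(nf) <= params$high_carb_families, 20, 5
  )
  protein_mean <- stats::runif(nf, 2, 12)
  fat_mean <- stats::runif(nf, 1, 10)
  lnoise <- function(n, sdlog = 0.12) exp(stats::rnorm(n, 0, sdlog))
  per_rows <- purrr::map_dfr(seq_len(nrow(ingredients)), function(k) {
    id <- ingredients$ingredient_id[[k]]
    f <- family_of[id]
    if (is.na(f)) { # staples: essentially nutrient-free
      amounts <- c(carbohydrate = 0, protein = 0, fat = 0, sodium = 20)
    } else {
      amounts <- c(
        carbohydrate = carb_mean[[f]] * lnoise(1),
        protein = protein_mean[[f]] * lnoise(1),
        fat = fat_mean[[f]] * lnoise(1),
        sodium = stats::runif(1, 1, 40)
      )
    }
    tibble::tibble(
      nutrition_id = ingredients$nutrition_id[[k]],
      nutrient = names(amounts),
      amount = round(unname(amounts), 2),
      unit = c("g", "g", "g", "mg")
    )
  })
  cu_rows <- purrr::map_dfr(ingredients$nutrition_id, function(nid) {
    tibble::tibble(
      nutrition_id = nid,
      description = c("1 cup", "1 tbsp"),
      grams = round(c(stats::runif(1, 90, 250), stats::runif(1, 8, 20)), 1)
    )
  })
  nutrition <- nutrition_table(per_rows, cu_rows)

  # --- recipes, sampled from family-slot templates --------------------
  # A template fixes which families co-occur; each recipe drawing it picks
  # one member per slot uniformly. Reusing templates makes recipe contexts
  # repeat across recipes, planting the context interchangeability the PPMI
  # score measures.
  n_templates <- max(6L, nf)
  templates <- purrr::map(seq_len(n_templates), function(tpl) {
    n_slots <- sample(seq(params$recipe_len[1], params$recipe_len[2]), 1)
    sample(seq_len(nf), min(n_slots, nf))
  })
  recs <- purrr::map(seq_len(params$n_recipes), function(r) {
    fams <- templates[[sample.int(n_templates, 1)]]
    picks <- vapply(fams, function(f) sample(draw_pools[[f]], 1), character(1))
    if (stats::runif(1) < params$noise_rate) {
      picks <- c(picks, sample(staple_names, sample(1:2, 1)))
    }
    qi <- purrr::map(picks, function(id) {
      u <- sample(c("cup", "tbsp", "g", ""), 1, prob = c(0.35, 0.25, 0.2, 0.2))
      list(
        ingredient_id = id,
        amount = if (u == "g") sample(50:400, 1) else sample(1:4, 1),
        unit = u
      )
    })
    verbs <- sample(cooking_verbs, 4, replace = TRUE)
    list(
      recipe_id = sprintf("r%04d", r),
      name = paste(picks[[1]], verbs[[1]]),
      ingredients = qi,
      servings = sample(2:6, 1),
      instructions = paste(
        sample(c(verbs, picks, verbs[1:2])),
        collapse = " "
      )
    )
  })
  recipes <- recipes_table(recs, ingredients)

  # --- ground truth: within-family directed pairs, never same-class ---
  class_of <- stats::setNames(ingredients$class_id, ingredients$ingredient_id)
  pairs <- purrr::map_dfr(seq_len(nf), function(f) {
    pool <- draw_pools[[f]]
    grid <- expand.grid(
      target_id = pool, substitute_id = pool,
      stringsAsFactors = FALSE
    )
    grid[
      grid$target_id != grid$substitute_id &
        class_of[grid$target_id] != class_of[grid$substitute_id], ,
      drop = FALSE
    ]
  })
  truth <- ground_truth(tibble::as_tibble(pairs))

  # --- reviews --------------------------------------------------------
  templates <- c(
    "i substituted %s for %s and it came out fine",
    "replaced the %s with %s last time and loved it",
    "we used %s instead of %s and nobody noticed"
  )
  review_lines <- purrr::map_chr(seq_len(nrow(truth$pairs)), function(k) {
    t <- truth$pairs$target_id[[k]]
    s <- truth$pairs$substitute_id[[k]]
    tpl <- sample(templates, 1)
    if (startsWith(tpl, "replaced")) sprintf(tpl, t, s) else sprintf(tpl, s, t)
  })
  reviews <- sample(c(
    review_lines,
    sample(distractor_lines, 30, replace = TRUE)
  ))

  # --- synthetic general-language vectors -----------------------------
  gdim <- 25
  fam_dir <- matrix(stats::rnorm(nf * gdim), nf, gdim) / sqrt(gdim)
  tokens <- c(ing_names, cooking_verbs)
  gvec <- t(vapply(tokens, function(tok) {
    f <- family_of[tok]
    base <- if (!is.na(f)) fam_dir[f, ] else stats::rnorm(gdim) / sqrt(gdim)
    base + 0.3 * stats::rnorm(gdim) / sqrt(gdim)
  }, numeric(gdim)))
  rownames(gvec) <- tokens
  general_vectors <- embedding_model(
    gvec,
    metadata = list(method = "synthetic-general", seed = params$seed)
  )

  structure(
    list(
      ontology = ont, ingredients = ingredients, recipes = recipes,
      nutrition = nutrition, truth = truth, reviews = reviews,
      general_vectors = general_vectors,
      manifest = unclass(params)
    ),
    class = "food_kg"
  )
}

#' Write a generated fixture bundle to a directory
#'
#' Writes the standard knowledge-graph files plus `general_vectors.txt`
#' (word2vec text format; synthetic) and `manifest.json` with the
#' generation parameters.
#'
#' @param kg Bundle from [generate_food_kg()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(kg, dir) {
  write_food_kg(kg, dir)
  if (!is.null(kg$general_vectors)) {
    write_word_vectors(kg$general_vectors, file.path(dir, "general_vectors.txt"))
  }
  if (!is.null(kg$manifest)) {
    jsonlite::write_json(
      kg$manifest, file.path(dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}

#' Fit all DIISH components over a knowledge graph
#'
#' Convenience wrapper that trains the corpus embedding, builds the
#' co-occurrence table and context statistics, resolves the general-language
#' provider (the bundle's `general_vectors` by default), and returns the
#' component-score provider along with the fitted pieces.
#'
#' @param kg A `food_kg` bundle.
#' @param general_model Optional `embedding_model` for the S score;
#'   defaults to `kg$general_vectors`, and to the corpus model's vocabulary
#'   with zero similarity contribution when neither is available.
#' @param embed_dim Corpus embedding dimension.
#' @param seed Seed recorded for the corpus embedding.
#' @param normalizer PPMI normaliser.
#' @return A list of class `diish_components`: `provider`, `corpus_model`,
#'   `general_model`, `cooccurrence`, `context_stats`.
#' @export
fit_diish_components <- function(kg, general_model = NULL, embed_dim = 64,
                                 seed = 1, normalizer = "max") {
  corpus_model <- train_corpus_embedding(
    kg$recipes, kg$ingredients,
    dim = embed_dim, seed = seed
  )
  general_model <- general_model %||% kg$general_vectors %||%
    embedding_model(
      matrix(0, 1, 1, dimnames = list("", NULL)),
      metadata = list(method = "null")
    )
  cooc <- build_cooccurrence(kg$recipes, kg$ingredients, kg$ontology)
  ctx <- suppressWarnings(
    collect_context_stats(kg$recipes, kg$ingredients, kg$ontology)
  )
  provider <- diish_score_provider(
    kg, corpus_model, general_model, cooc, ctx,
    normalizer = normalizer
  )
  structure(
    list(
      provider = provider, corpus_model = corpus_model,
      general_model = general_model, cooccurrence = cooc,
      context_stats = ctx
    ),
    class = "diish_components"
  )
}
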