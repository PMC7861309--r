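test_that("gram conversion follows mass-unit, description-match, default order", {
  cu <- tibble::tibble(
    description = c("1 tsp", "1 tbsp"),
    grams = c(4.3, 13)
  )
  expect_equal(to_grams(1, "kg", cu), 1000)
  expect_equal(to_grams(250, "g", cu), 250)
  expect_equal(to_grams(2, "oz", cu), 2 * 28.3495)
  # description substring match fires before the first-unit default
  expect_equal(to_grams(6, "tsp", cu), 25.8, tolerance = 1e-9)
  expect_equal(to_grams(1, "tbsp", cu), 13)
  # no match and empty unit fall back to the first common unit
  first_default <- tibble::tibble(description = "1 whole", grams = 58)
  expect_equal(to_grams(2, "whole no match here", cu), 2 * 4.3)
  expect_equal(to_grams(2, "bunch", first_default), 116)
  expect_equal(to_grams(2, "", first_default), 116)
  # absent amount contributes zero
  expect_equal(to_grams(NA_real_, "cup", cu), 0)
  expect_error(
    to_grams(1, "cup", cu[0, ]),
    class = "substkg_validation_error"
  )
})

test_that("recipe nutrition reproduces the roasted-potato worked example", {
  kg <- roast_potato_kg()
  bd <- recipe_nutrients(kg$recipes[1, ], kg$nutrition, kg$ingredients)
  per <- bd$per_ingredient
  carb <- function(id) sum(per$amount[per$ingredient_id == id & per$nutrient == "carbohydrate"])
  expect_equal(carb("potatoes"), 175.0, tolerance = 1e-9)
  expect_equal(round(carb("lemon"), 1), 10.8)
  expect_equal(carb("black pepper"), 0)
  expect_equal(carb("coarse sea salt"), 0)
  expect_equal(carb("olive oil"), 0)
  expect_equal(per$grams[per$ingredient_id == "lemon"][[1]], 116)
  expect_equal(per$grams[per$ingredient_id == "red onion"][[1]], 480)
  expect_equal(per$grams[per$ingredient_id == "olive oil"][[1]], 26)
  # per-serving totals divide by declared servings
  expect_equal(
    bd$per_serving[["carbohydrate"]],
    bd$recipe_totals[["carbohydrate"]] / 4
  )
  # quantified ingredient without a nutrition record is an error naming it
  ing2 <- kg$ingredients
  ing2$nutrition_id[ing2$ingredient_id == "potatoes"] <- NA
  expect_error(
    recipe_nutrients(kg$recipes[1, ], kg$nutrition, ing2),
    regexp = "potatoes"
  )
})

test_that("recipe totals conserve the per-ingredient sums", {
  kg <- default_fixture()
  for (k in c(1, 5, 9)) {
    bd <- recipe_nutrients(kg$recipes[k, ], kg$nutrition, kg$ingredients)
    for (n in names(bd$recipe_totals)) {
      expect_equal(
        bd$recipe_totals[[n]],
        sum(bd$per_ingredient$amount[bd$per_ingredient$nutrient == n]),
        tolerance = 1e-9
      )
    }
  }
})

test_that("restriction checks traverse subClassOf and derivesFrom paths", {
  # bacon subClassOf pork product; pork product derivesFrom meat
  ont <- ontology(tibble::tibble(
    child = c("bacon", "pork product", "tofu"),
    relation = c("subClassOf", "derivesFrom", "subClassOf"),
    parent = c("pork product", "meat", "plant protein")
  ))
  ing <- ingredients_table(tibble::tibble(
    ingredient_id = c("i_bacon", "i_tofu", "i_mystery"),
    name = c("bacon", "tofu", "mystery"),
    class_id = c("bacon", "tofu", ""),
    nutrition_id = ""
  ), ont)
  meat_free <- dietary_profile(prohibited_classes = "meat")
  expect_true(violates_restriction("i_bacon", meat_free, ont, ing))
  expect_false(violates_restriction("i_tofu", meat_free, ont, ing))
  expect_false(violates_restriction("i_mystery", meat_free, ont, ing))
  # prohibiting the ingredient's own class violates directly
  expect_true(violates_restriction(
    "i_bacon", dietary_profile(prohibited_classes = "bacon"), ont, ing
  ))
  expect_error(
    violates_restriction(
      "i_bacon", dietary_profile(prohibited_classes = "unicorn"), ont, ing
    ),
    class = "substkg_parameter_error"
  )
})

test_that("prohibiting an ancestor prohibits every descendant (monotonicity)", {
  skip_if_not_installed("igraph")
  edges <- random_dag_edges(10, 17)
  ont <- ontology(edges)
  classes <- class_ids(ont)
  ing <- ingredients_table(tibble::tibble(
    ingredient_id = paste0("i_", classes), name = classes,
    class_id = classes, nutrition_id = ""
  ), ont)
  for (root in classes[1:3]) {
    profile <- dietary_profile(prohibited_classes = root)
    for (cls in c(root, igraph_reachable(edges, root, "in"))) {
      expect_true(violates_restriction(paste0("i_", cls), profile, ont, ing))
    }
  }
})

test_that("top contributors rank by amount with id tie-breaks", {
  kg <- roast_potato_kg()
  bd <- recipe_nutrients(kg$recipes[1, ], kg$nutrition, kg$ingredients)
  tc <- top_contributors(bd, "carbohydrate")
  expect_equal(tc$ingredient_id[[1]], "potatoes")
  expect_equal(tc$amount, sort(tc$amount, decreasing = TRUE))
  # the zero contributors tie and sort by id
  zeros <- tc$ingredient_id[tc$amount == 0]
  expect_equal(zeros, sort(zeros))
  expect_error(top_contributors(bd, "protein"), class = "substkg_lookup_error")

  toy <- structure(
    list(
      recipe_id = "toy",
      per_ingredient = tibble::tibble(
        ingredient_id = c("a", "b", "c"),
        grams = 100,
        nutrient = "fiber",
        amount = c(5, 3, 9)
      ),
      recipe_totals = c(fiber = 17)
    ),
    class = "nutrient_breakdown"
  )
  expect_equal(top_contributors(toy, "fiber")$ingredient_id, c("c", "a", "b"))
})

test_that("healthy candidates require strictly fewer carbs and no violations", {
  kg <- roast_potato_kg()
  profile <- dietary_profile(reduce_nutrients = "carbohydrate")
  kept <- healthy_candidates(
    "potatoes", c("turnip", "cauliflower", "squash", "lemon", "red onion"),
    "carbohydrate", kg$nutrition, profile, kg$ontology, kg$ingredients
  )
  # all have < 17.5 g/100 g, so all survive
  expect_setequal(kept, c("turnip", "cauliflower", "squash", "lemon", "red onion"))

  # candidate equal to the target is dropped (strict inequality)
  nut2 <- kg$nutrition
  nut2$per_100g$amount[nut2$per_100g$nutrition_id == "n_tur"] <- 17.5
  kept2 <- healthy_candidates(
    "potatoes", c("turnip", "cauliflower"), "carbohydrate",
    nut2, profile, kg$ontology, kg$ingredients
  )
  expect_setequal(kept2, "cauliflower")

  # a prohibited class drops a candidate regardless of its nutrient level
  profile3 <- dietary_profile(
    prohibited_classes = "turnip class",
    reduce_nutrients = "carbohydrate"
  )
  kept3 <- healthy_candidates(
    "potatoes", c("turnip", "cauliflower"), "carbohydrate",
    kg$nutrition, profile3, kg$ontology, kg$ingredients
  )
  expect_setequal(kept3, "cauliflower")

  expect_error(
    healthy_candidates(
      "black pepper", "turnip", "sugar",
      kg$nutrition, profile, kg$ontology, kg$ingredients
    ),
    class = "substkg_validation_error"
  )
})

test_that("healthy candidate survivors are always strictly lower (random tables)", {
  withr::with_seed(55, {
    for (rep in 1:5) {
      ids <- paste0("i", 1:8)
      ont <- ontology()
      ing <- ingredients_table(tibble::tibble(
        ingredient_id = ids, name = ids, class_id = "",
        nutrition_id = paste0("n", 1:8)
      ), ont)
      per <- tibble::tibble(
        nutrition_id = paste0("n", 1:8),
        nutrient = "carbohydrate",
        amount = round(stats::runif(8, 0, 30), 1),
        unit = "g"
      )
      nut <- nutrition_table(per, tibble::tibble(
        nutrition_id = character(), description = character(), grams = numeric()
      ))
      profile <- dietary_profile(reduce_nutrients = "carbohydrate")
      target <- ids[[1]]
      kept <- healthy_candidates(
        target, ids[-1], "carbohydrate", nut, profile, ont, ing
      )
      expect_true(all(kept %in% ids[-1]))
      tgt_amt <- per$amount[[1]]
      for (cand in kept) {
        expect_lt(per$amount[[match(cand, ids)]], tgt_amt)
      }
      should_keep <- ids[-1][per$amount[-1] < tgt_amt]
      expect_setequal(kept, should_keep)
    }
  })
})

test_that("the suggestion engine flags top contributors and ranks healthy substitutes", {
  kg <- roast_potato_kg()
  # a flat provider: every candidate equally plausible, ranking by id
  flat <- function(target, candidates) {
    tibble::tibble(candidate_id = candidates, W = 0.5, S = 0.5, D = 0.5, P = 0.5)
  }
  profile <- dietary_profile(reduce_nutrients = "carbohydrate")
  report <- suggest_substitutions(
    kg$recipes[1, ], profile, kg, flat,
    candidates = kg$ingredients$ingredient_id
  )
  expect_equal(report$ingredient_id, "potatoes")
  expect_equal(report$reason, "nutrient:carbohydrate")
  subs <- report$substitutes[[1]]
  expect_gt(nrow(subs), 0)
  carbs <- stats::setNames(
    kg$nutrition$per_100g$amount, kg$nutrition$per_100g$nutrition_id
  )
  nid <- stats::setNames(kg$ingredients$nutrition_id, kg$ingredients$ingredient_id)
  for (cand in subs$candidate_id) {
    expect_lt(carbs[[nid[[cand]]]], 17.5)
  }

  # no constraints: nothing flagged
  empty <- suggest_substitutions(
    kg$recipes[1, ], dietary_profile(), kg, flat
  )
  expect_equal(nrow(empty), 0)

  # an unquantified violator is flagged via the restriction path
  profile2 <- dietary_profile(prohibited_classes = "pepper class")
  report2 <- suggest_substitutions(kg$recipes[1, ], profile2, kg, flat)
  expect_equal(report2$ingredient_id, "black pepper")
  expect_equal(report2$reason, "restriction")
})
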