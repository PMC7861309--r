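test_that("combine_scores reproduces hand-computed power sums", {
  scores <- c(W = 0.5, S = 0.4, D = 0.8, P = 0.3)
  expect_equal(
    combine_scores(scores, diish_spec(c(1, 0.5, 0.5, 2), c(1, 1, 1 / 4, 1))),
    0.5 + 0.2 + 0.5 * 0.8^0.25 + 0.6,
    tolerance = 1e-9
  )
  expect_equal(
    combine_scores(scores, default_diish_spec()), 1.7728,
    tolerance = 1e-4
  )
  expect_equal(
    combine_scores(scores, alt_diish_spec()), 1.5048,
    tolerance = 1e-4
  )
  zero <- c(W = 0, S = 0, D = 0, P = 0)
  expect_equal(combine_scores(zero, default_diish_spec()), 0)
  # negative components are clamped before fractional powers only
  neg <- c(W = -0.5, S = 0.4, D = 0.8, P = 0.3)
  frac <- diish_spec(c(1, 1, 1, 1), c(1 / 2, 1, 1, 1))
  expect_equal(combine_scores(neg, frac), 0 + 0.4 + 0.8 + 0.3)
  intp <- diish_spec(c(1, 1, 1, 1), c(2, 1, 1, 1))
  expect_equal(combine_scores(neg, intp), 0.25 + 0.4 + 0.8 + 0.3)
})

test_that("combine_scores is monotone and bounded for positive coefficients", {
  withr::with_seed(31, {
    for (rep in 1:200) {
      spec <- diish_spec(
        sample(c(0.5, 1, 2, 4), 4, replace = TRUE),
        sample(c(1 / 4, 1 / 2, 1, 2), 4, replace = TRUE)
      )
      lo <- stats::runif(4)
      hi <- pmin(lo + stats::runif(4, 0, 0.3), 1)
      names(lo) <- names(hi) <- c("W", "S", "D", "P")
      expect_lte(combine_scores(lo, spec), combine_scores(hi, spec) + 1e-12)
      # scores in [0,1] keep the combined value within the coefficient sum
      expect_lte(combine_scores(hi, spec), sum(spec$coefficients) + 1e-12)
      expect_gte(combine_scores(lo, spec), 0)
    }
  })
})

test_that("hierarchy filtering removes exactly self, ancestors and descendants", {
  # 5-class toy tree: gp -> p -> {t, sib}; child -> t
  ont <- ont_from_edges(
    c("p", "t", "sib", "child"),
    c("gp", "p", "p", "t")
  )
  ing <- ingredients_table(tibble::tibble(
    ingredient_id = c("i_t", "i_p", "i_gp", "i_sib", "i_child", "i_same", "i_free"),
    name = c("t", "p", "gp", "sib", "child", "same", "free"),
    class_id = c("t", "p", "gp", "sib", "child", "t", ""),
    nutrition_id = ""
  ), ont)
  cands <- ing$ingredient_id
  kept <- filter_hierarchy("i_t", cands, ont, ing)
  expect_false("i_t" %in% kept) # self
  expect_false("i_p" %in% kept) # parent class
  expect_false("i_gp" %in% kept) # transitive ancestor
  expect_false("i_child" %in% kept) # descendant
  expect_false("i_same" %in% kept) # same class
  expect_true("i_sib" %in% kept) # sibling retained
  expect_true("i_free" %in% kept) # unlinked passes

  expect_warning(
    kept2 <- filter_hierarchy("i_free", cands, ont, ing),
    regexp = "self-removal"
  )
  expect_setequal(kept2, setdiff(cands, "i_free"))
})

test_that("hierarchy filtering equals a closure oracle on random DAGs", {
  skip_if_not_installed("igraph")
  for (seed in 6:9) {
    edges <- random_dag_edges(10, seed)
    ont <- ontology(edges)
    classes <- class_ids(ont)
    withr::with_seed(seed, {
      ids <- paste0("i", seq_along(classes))
      ing <- ingredients_table(tibble::tibble(
        ingredient_id = ids, name = ids,
        class_id = sample(classes), nutrition_id = ""
      ), ont)
    })
    target <- ids[[1]]
    kept <- filter_hierarchy(target, ids, ont, ing)
    tc <- ing$class_id[[1]]
    related <- c(
      tc, igraph_reachable(edges, tc, "out"), igraph_reachable(edges, tc, "in")
    )
    oracle <- setdiff(ids[!(ing$class_id %in% related)], target)
    expect_setequal(kept, oracle)
  }
})

test_that("rank_substitutes orders by score with deterministic tie-breaks", {
  tables <- list(t = tibble::tibble(
    candidate_id = c("c1", "c2", "c3", "c4", "c5", "c6"),
    W = c(0.9, 0.1, 0.9, 0.5, 0.2, 0.4),
    S = 0, D = 0, P = 0
  ))
  prov <- manual_provider(tables)
  spec <- diish_spec(c(1, 0, 0, 0), c(1, 1, 1, 1))

  single <- rank_substitutes("t", "c1", prov, spec, hierarchy_filter = FALSE)
  expect_equal(single$candidate_id, "c1")

  ranked <- rank_substitutes(
    "t", paste0("c", 1:6), prov, spec,
    hierarchy_filter = FALSE
  )
  # brute-force sort oracle over (score desc, id asc)
  oracle <- tables$t[order(-tables$t$W, tables$t$candidate_id), ]$candidate_id
  expect_equal(ranked$candidate_id, oracle)
  expect_equal(ranked$candidate_id[1:2], c("c1", "c3")) # tie broken by id

  empty <- rank_substitutes("t", character(), prov, spec, hierarchy_filter = FALSE)
  expect_equal(nrow(empty), 0)
})

test_that("ranking never emits hierarchy-related candidates when filtering", {
  kg <- default_fixture()
  comp <- default_components()
  pool <- kg$truth$candidate_pool
  for (target in pool[1:5]) {
    ranked <- rank_substitutes(
      target, pool, comp$provider,
      ont = kg$ontology, ingredients = kg$ingredients
    )
    tc <- kg$ingredients$class_id[kg$ingredients$ingredient_id == target]
    for (cand in ranked$candidate_id) {
      cc <- kg$ingredients$class_id[kg$ingredients$ingredient_id == cand]
      expect_false(hierarchy_related(kg$ontology, cc, tc))
    }
  }
})

test_that("the default grids enumerate 16^4 combinations", {
  grid <- enumerate_diish_grid()
  expect_equal(nrow(grid), 65536)
  expect_equal(nrow(dplyr::distinct(grid)), 65536)
  small <- enumerate_diish_grid(coefficients = c(1, 2), powers = c(1, 2))
  expect_equal(nrow(small), 2^4 * 2^4)
})

test_that("grid search returns the argmax of an exhaustive re-evaluation", {
  # two targets with known relevant candidates and fixed component scores
  tables <- list(
    t1 = tibble::tibble(
      candidate_id = c("a", "b", "c"),
      W = c(0.9, 0.2, 0.5), S = c(0.1, 0.8, 0.3),
      D = c(0.2, 0.3, 0.9), P = c(0.5, 0.1, 0.2)
    ),
    t2 = tibble::tibble(
      candidate_id = c("a", "b", "c"),
      W = c(0.1, 0.7, 0.3), S = c(0.9, 0.2, 0.1),
      D = c(0.4, 0.8, 0.1), P = c(0.2, 0.6, 0.9)
    )
  )
  prov <- manual_provider(tables)
  truth <- ground_truth(
    tibble::tibble(
      target_id = c("t1", "t2", "t2"),
      substitute_id = c("c", "b", "a")
    ),
    candidate_pool = c("a", "b", "c", "t1", "t2")
  )
  coefs <- c(0.5, 2)
  pows <- c(1 / 2, 2)
  gs <- grid_search_diish(
    truth, prov,
    objective = "map",
    coefficients = coefs, powers = pows, hierarchy_filter = FALSE
  )
  expect_equal(gs$n_combinations, 2^8)

  # independent oracle: evaluate every spec via the public ranking path
  grid <- enumerate_diish_grid(coefs, pows)
  oracle_map <- vapply(seq_len(nrow(grid)), function(r) {
    spec <- diish_spec(
      c(grid$cW[r], grid$cS[r], grid$cD[r], grid$cP[r]),
      c(grid$pW[r], grid$pS[r], grid$pD[r], grid$pP[r])
    )
    aps <- vapply(c("t1", "t2"), function(t) {
      rel <- truth$pairs$substitute_id[truth$pairs$target_id == t]
      ranked <- rank_substitutes(
        t, setdiff(truth$candidate_pool, t), prov, spec,
        hierarchy_filter = FALSE
      )
      average_precision(ranked$candidate_id, rel)
    }, numeric(1))
    mean(aps)
  }, numeric(1))
  expect_equal(gs$grid$objective, oracle_map, tolerance = 1e-12)
  best <- which.max(oracle_map)
  expect_equal(gs$objective, oracle_map[[best]], tolerance = 1e-12)
  expect_equal(
    unname(gs$spec$coefficients),
    as.numeric(grid[best, c("cW", "cS", "cD", "cP")])
  )
  expect_equal(
    unname(gs$spec$powers),
    as.numeric(grid[best, c("pW", "pS", "pD", "pP")])
  )

  # singleton grids return the unique spec
  one <- grid_search_diish(
    truth, prov,
    coefficients = 1, powers = 1, hierarchy_filter = FALSE
  )
  expect_equal(unname(one$spec$coefficients), rep(1, 4))
  expect_equal(unname(one$spec$powers), rep(1, 4))
  expect_equal(one$n_combinations, 1)
})

test_that("grid search supports mrr and rr@k objectives and rejects others", {
  tables <- list(t1 = tibble::tibble(
    candidate_id = c("a", "b"), W = c(0.2, 0.9), S = 0, D = 0, P = 0
  ))
  prov <- manual_provider(tables)
  truth <- ground_truth(
    tibble::tibble(target_id = "t1", substitute_id = "a"),
    candidate_pool = c("a", "b", "t1")
  )
  gs <- grid_search_diish(
    truth, prov,
    objective = "mrr", coefficients = 1, powers = 1,
    hierarchy_filter = FALSE
  )
  expect_equal(gs$objective, 0.5) # "a" forced to rank 2
  gs2 <- grid_search_diish(
    truth, prov,
    objective = "rr@k", k = 1, coefficients = 1, powers = 1,
    hierarchy_filter = FALSE
  )
  expect_equal(gs2$objective, 0)
  expect_error(
    grid_search_diish(truth, prov, objective = "ndcg"),
    regexp = "should be one of"
  )
})

test_that("dev/eval splitting excludes dev targets from evaluation", {
  kg <- default_fixture()
  split <- split_dev_targets(kg$truth, n_dev = 10, seed = 4)
  dev_targets <- unique(split$dev$pairs$target_id)
  expect_length(dev_targets, 10)
  expect_length(
    intersect(dev_targets, unique(split$eval$pairs$target_id)), 0
  )
  # both halves keep the full candidate pool
  expect_equal(split$dev$candidate_pool, kg$truth$candidate_pool)
  # deterministic under the seed
  split2 <- split_dev_targets(kg$truth, n_dev = 10, seed = 4)
  expect_equal(split$dev$pairs, split2$dev$pairs)
})
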