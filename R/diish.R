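#' Specify a DIISH score combination
#'
#' DIISH combines the four pairwise scores -- corpus-embedding cosine `W`,
#' general-embedding cosine `S`, co-occurrence cosine `D`, and PPMI context
#' cosine `P` -- as a weighted power sum
#' `sum_m coefficient_m * score_m ^ power_m` with the metric order fixed at
#' (W, S, D, P).
#'
#' @param coefficients Numeric vector of length 4 (order W, S, D, P).
#' @param powers Numeric vector of length 4 (order W, S, D, P).
#' @return A `diish_spec`.
#' @export
diish_spec <- function(coefficients, powers) {
  coefficients <- as.numeric(coefficients)
  powers <- as.numeric(powers)
  if (length(coefficients) != 4 || length(powers) != 4) {
    abort_parameter("a DIISH spec needs 4 coefficients and 4 powers (W, S, D, P)")
  }
  structure(
    list(
      coefficients = stats::setNames(coefficients, c("W", "S", "D", "P")),
      powers = stats::setNames(powers, c("W", "S", "D", "P"))
    ),
    class = "diish_spec"
  )
}

#' @export
print.diish_spec <- function(x, ...) {
  terms <- paste0(
    format(x$coefficients, trim = TRUE), "*",
    names(x$coefficients), "^", format(x$powers, trim = TRUE)
  )
  cat("<diish_spec> ", paste(terms, collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' Default and alternative DIISH combination presets
#'
#' The heuristic's conventional formula, `W + S/2 + (1/2) D^(1/4) + 2 P`,
#' is ambiguous in its D exponent as usually typeset (1/4 vs 4). The default
#' preset reads the exponent as 1/4, consistent with the tuning power grid
#' (which contains 1/4 but not 4); the `alt` preset carries the other
#' reading, `W + S/2 + (1/2) D^4 + 2 P`.
#'
#' @return A `diish_spec`.
#' @export
default_diish_spec <- function() {
  diish_spec(c(1, 0.5, 0.5, 2), c(1, 1, 1 / 4, 1))
}

#' @rdname default_diish_spec
#' @export
alt_diish_spec <- function() {
  diish_spec(c(1, 0.5, 0.5, 2), c(1, 1, 4, 1))
}

#' Combine component scores into a DIISH value
#'
#' Negative component values (possible for the embedding cosines W and S)
#' are clamped to 0 before a non-integer power is applied, so fractional
#' exponents stay real-valued; integer powers use the raw value.
#'
#' @param scores Named numeric vector (or list) with elements `W`, `S`, `D`,
#'   `P`.
#' @param spec A `diish_spec`.
#' @return A single DIISH score.
#' @export
#' @examples
#' combine_scores(
#'   c(W = 0.5, S = 0.4, D = 0.8, P = 0.3),
#'   default_diish_spec()
#' )
combine_scores <- function(scores, spec) {
  s <- unlist(scores)[c("W", "S", "D", "P")]
  sum(spec$coefficients * power_clamped(s, spec$powers))
}

power_clamped <- function(x, p) {
  frac <- p %% 1 != 0
  x[frac] <- pmax(x[frac], 0)
  x^p
}

# matrix variant: rows = candidates, cols = W, S, D, P
combine_matrix <- function(m, spec) {
  out <- numeric(nrow(m))
  for (j in seq_len(4)) {
    v <- m[, j]
    if (spec$powers[[j]] %% 1 != 0) v <- pmax(v, 0)
    out <- out + spec$coefficients[[j]] * v^spec$powers[[j]]
  }
  out
}

#' Remove super/subclass (and self) substitution candidates
#'
#' A specific variety is not a useful substitute for its own general class
#' and vice versa, so candidates whose class lies on a `subClassOf` path
#' through the target's class (including the same class) are removed. The
#' target itself is always removed. Candidates without a class link pass
#' unfiltered; a target without a class link degenerates the filter to
#' self-removal (with a warning).
#'
#' @param target Target ingredient id.
#' @param candidates Character vector of candidate ingredient ids.
#' @param ont A `food_ontology`.
#' @param ingredients Ingredient table carrying the class links.
#' @return Character vector of retained candidate ids.
#' @export
filter_hierarchy <- function(target, candidates, ont, ingredients) {
  candidates <- setdiff(candidates, target)
  tc <- ingredient_class(ingredients, target)
  if (is.na(tc)) {
    rlang::warn(paste0(
      "target '", target, "' has no class link; hierarchy filter reduced to self-removal"
    ))
    return(candidates)
  }
  related_classes <- c(
    tc,
    ancestors(ont, tc, "subClassOf"),
    descendants(ont, tc, "subClassOf")
  )
  cc <- ingredient_class(ingredients, candidates)
  keep <- is.na(cc) | !(cc %in% related_classes)
  candidates[keep]
}

#' Build a DIISH component-score provider over a knowledge graph
#'
#' Returns a function `(target, candidates) -> tibble(candidate_id, W, S, D,
#' P)` that computes all four component scores, with per-ingredient
#' embedding and PPMI vectors precomputed and cached so repeated calls (for
#' instance across grid-search combinations) are cheap. `S` falls back to 0
#' for names absent from the general vector table; `P` is 0 for ingredients
#' without a class link.
#'
#' @param kg A `food_kg` bundle (or any list with `ingredients`).
#' @param corpus_model `embedding_model` trained on the recipe corpus (W).
#' @param general_model `embedding_model` from a general-language vector
#'   table (S).
#' @param cooccurrence A `cooccurrence_table` (D).
#' @param context_stats A `context_stats` object (P).
#' @param normalizer PPMI normaliser, `"max"` or `"total"`.
#' @return A score-provider function.
#' @export
diish_score_provider <- function(kg, corpus_model, general_model,
                                 cooccurrence, context_stats,
                                 normalizer = "max") {
  ingredients <- kg$ingredients
  ids <- ingredients$ingredient_id
  name_of <- stats::setNames(ingredients$name, ids)
  class_of <- stats::setNames(ingredients$class_id, ids)

  unit_rows <- function(model) {
    m <- t(vapply(
      ids,
      function(id) name_vector(model, name_of[[id]]),
      numeric(model$dimension)
    ))
    nrm <- sqrt(rowSums(m^2))
    m[nrm > 0, ] <- m[nrm > 0, , drop = FALSE] / nrm[nrm > 0]
    rownames(m) <- ids
    m
  }
  w_mat <- unit_rows(corpus_model)
  s_mat <- unit_rows(general_model)

  cm <- cooccurrence$counts
  d_nrm <- sqrt(Matrix::rowSums(cm^2))
  d_mat <- Matrix::Diagonal(x = ifelse(d_nrm > 0, 1 / d_nrm, 0)) %*% cm
  dimnames(d_mat) <- dimnames(cm)

  p_cache <- new.env(parent = emptyenv())
  p_unit <- function(cls) {
    if (is.na(cls)) {
      return(NULL)
    }
    if (is.null(p_cache[[cls]])) {
      v <- ppmi_vector(context_stats, cls, normalizer)
      nrm <- sqrt(sum(v^2))
      p_cache[[cls]] <- if (nrm > 0) v / nrm else v
    }
    p_cache[[cls]]
  }

  function(target, candidates) {
    if (!target %in% ids || !all(candidates %in% ids)) {
      abort_lookup("score provider: unknown ingredient id")
    }
    w <- as.numeric(w_mat[candidates, , drop = FALSE] %*% w_mat[target, ])
    s <- as.numeric(s_mat[candidates, , drop = FALSE] %*% s_mat[target, ])
    d <- as.numeric(d_mat[candidates, , drop = FALSE] %*% d_mat[target, ])
    tv <- p_unit(class_of[[target]])
    p <- if (is.null(tv)) {
      numeric(length(candidates))
    } else {
      vapply(candidates, function(cand) {
        cv <- p_unit(class_of[[cand]])
        if (is.null(cv)) 0 else sum(tv * cv)
      }, numeric(1))
    }
    tibble::tibble(candidate_id = candidates, W = w, S = s, D = d, P = p)
  }
}

#' Rank substitution candidates for a target ingredient
#'
#' Applies the hierarchy filter (when enabled), scores the surviving
#' candidates with [combine_scores()] under `spec`, and orders them by
#' descending score with ties broken by ascending ingredient id. An empty
#' post-filter candidate set yields an empty ranking, not an error.
#'
#' @param target Target ingredient id.
#' @param candidates Character vector of candidate ids.
#' @param score_provider Function from [diish_score_provider()] (or any
#'   function with the same contract).
#' @param spec A `diish_spec`.
#' @param ont,ingredients Ontology and ingredient table, required when
#'   `hierarchy_filter` is TRUE.
#' @param hierarchy_filter Apply super/subclass filtering (default TRUE).
#' @return A tibble of class `ranked_list` with columns `candidate_id`,
#'   `score` and components `W`, `S`, `D`, `P`; the target id is attached as
#'   attribute `target`.
#' @export
rank_substitutes <- function(target, candidates, score_provider,
                             spec = default_diish_spec(),
                             ont = NULL, ingredients = NULL,
                             hierarchy_filter = TRUE) {
  candidates <- setdiff(unique(candidates), target)
  if (hierarchy_filter) {
    if (is.null(ont) || is.null(ingredients)) {
      abort_parameter("hierarchy filtering needs `ont` and `ingredients`")
    }
    candidates <- filter_hierarchy(target, candidates, ont, ingredients)
  }
  if (length(candidates) == 0) {
    out <- tibble::tibble(
      candidate_id = character(), score = numeric(),
      W = numeric(), S = numeric(), D = numeric(), P = numeric()
    )
    return(as_ranked_list(out, target))
  }
  comp <- score_provider(target, candidates)
  comp$score <- combine_matrix(as.matrix(comp[, c("W", "S", "D", "P")]), spec)
  out <- comp[order(-comp$score, comp$candidate_id), ]
  out <- out[, c("candidate_id", "score", "W", "S", "D", "P")]
  as_ranked_list(out, target)
}

as_ranked_list <- function(tb, target) {
  structure(tb, target = target, class = c("ranked_list", class(tb)))
}

#' Enumerate the DIISH coefficient/power grid
#'
#' The default grids (coefficients from \{0.5, 1, 2, 4\} and powers from
#' \{1/4, 1/2, 1, 2\}, independently per metric) enumerate 16^4 = 65,536
#' combinations. Enumeration order is deterministic: the first column varies
#' fastest.
#'
#' @param coefficients Coefficient grid (shared by all four metrics).
#' @param powers Power grid (shared by all four metrics).
#' @return A tibble with columns `cW, cS, cD, cP, pW, pS, pD, pP`, one row
#'   per combination.
#' @export
enumerate_diish_grid <- function(coefficients = c(0.5, 1, 2, 4),
                                 powers = c(1 / 4, 1 / 2, 1, 2)) {
  tibble::as_tibble(expand.grid(
    cW = coefficients, cS = coefficients, cD = coefficients, cP = coefficients,
    pW = powers, pS = powers, pD = powers, pP = powers,
    KEEP.OUT.ATTRS = FALSE
  ))
}

grid_row_spec <- function(row) {
  diish_spec(
    c(row$cW, row$cS, row$cD, row$cP),
    c(row$pW, row$pS, row$pD, row$pP)
  )
}

#' Grid-search the DIISH combination on a development set
#'
#' Exhaustively evaluates every coefficient/power combination on the
#' development ground truth, scoring each combination by a ranking
#' objective, and returns the argmax (ties resolved to the first combination
#' in enumeration order). Component scores are computed once per target and
#' reused across all combinations.
#'
#' @param dev A `ground_truth` development set.
#' @param score_provider Component-score provider function.
#' @param objective `"map"`, `"mrr"` or `"rr@k"` (with `k` below).
#' @param k Cutoff for the `"rr@k"` objective.
#' @param coefficients,powers Grids, defaulting to the standard sets.
#' @param ont,ingredients Needed when `hierarchy_filter` is TRUE.
#' @param hierarchy_filter Apply super/subclass filtering while ranking.
#' @return A list of class `diish_grid_search`: `spec` (best
#'   `diish_spec`), `objective`, `objective_name`, `n_combinations`, and
#'   `grid` (the enumerated grid with an `objective` column).
#' @export
grid_search_diish <- function(dev, score_provider,
                              objective = c("map", "mrr", "rr@k"), k = 5,
                              coefficients = c(0.5, 1, 2, 4),
                              powers = c(1 / 4, 1 / 2, 1, 2),
                              ont = NULL, ingredients = NULL,
                              hierarchy_filter = TRUE) {
  objective <- match.arg(objective)
  targets <- sort(unique(dev$pairs$target_id))
  if (length(targets) == 0) abort_parameter("empty development set")

  # per-target component matrices and bookkeeping, computed once
  per_target <- purrr::map(targets, function(t) {
    cands <- setdiff(dev$candidate_pool, t)
    if (hierarchy_filter) {
      cands <- filter_hierarchy(t, cands, ont, ingredients)
    }
    relevant <- dev$pairs$substitute_id[dev$pairs$target_id == t]
    comp <- if (length(cands) > 0) {
      as.matrix(score_provider(t, cands)[, c("W", "S", "D", "P")])
    } else {
      matrix(numeric(0), 0, 4)
    }
    list(
      candidates = cands, comp = comp,
      rel_idx = match(intersect(relevant, cands), cands),
      n_relevant = length(relevant)
    )
  })

  n_coef <- length(coefficients)
  n_pow <- length(powers)
  coef_grid <- as.matrix(expand.grid(
    cW = coefficients, cS = coefficients, cD = coefficients, cP = coefficients,
    KEEP.OUT.ATTRS = FALSE
  ))
  pow_grid <- as.matrix(expand.grid(
    pW = powers, pS = powers, pD = powers, pP = powers,
    KEEP.OUT.ATTRS = FALSE
  ))
  n_cc <- nrow(coef_grid)
  tc <- t(coef_grid)

  objective_values <- numeric(n_cc * nrow(pow_grid))
  for (pb in seq_len(nrow(pow_grid))) {
    pw <- pow_grid[pb, ]
    acc <- numeric(n_cc)
    for (pt in per_target) {
      if (length(pt$rel_idx) == 0 || nrow(pt$comp) == 0) next
      b <- pt$comp
      for (j in seq_len(4)) {
        v <- b[, j]
        if (pw[[j]] %% 1 != 0) v <- pmax(v, 0)
        b[, j] <- v^pw[[j]]
      }
      sc <- b %*% tc # candidates x coefficient-combos
      ranks <- relevant_ranks(sc, pt$candidates, pt$rel_idx)
      acc <- acc + objective_from_ranks(ranks, pt$n_relevant, objective, k)
    }
    block <- seq.int((pb - 1) * n_cc + 1, pb * n_cc)
    objective_values[block] <- acc / length(targets)
  }

  grid <- enumerate_diish_grid(coefficients, powers)
  grid$objective <- objective_values
  best <- which.max(objective_values)
  structure(
    list(
      spec = grid_row_spec(grid[best, ]),
      objective = objective_values[[best]],
      objective_name = if (objective == "rr@k") paste0("rr@", k) else objective,
      n_combinations = nrow(grid),
      grid = grid
    ),
    class = "diish_grid_search"
  )
}

# ranks of the relevant candidates in each score column, honouring the
# (score desc, id asc) tie rule
relevant_ranks <- function(sc, candidates, rel_idx) {
  n_spec <- ncol(sc)
  ranks <- matrix(0L, length(rel_idx), n_spec)
  for (m in seq_along(rel_idx)) {
    r <- rel_idx[[m]]
    sr <- sc[r, ]
    greater <- colSums(sc > matrix(sr, nrow(sc), n_spec, byrow = TRUE))
    id_lt <- candidates < candidates[[r]]
    ties <- colSums(
      (sc == matrix(sr, nrow(sc), n_spec, byrow = TRUE)) & id_lt
    )
    ranks[m, ] <- 1L + greater + ties
  }
  ranks
}

objective_from_ranks <- function(ranks, n_relevant, objective, k) {
  n_spec <- ncol(ranks)
  if (nrow(ranks) == 0) {
    return(numeric(n_spec))
  }
  if (objective == "map") {
    ap <- numeric(n_spec)
    for (j in seq_len(nrow(ranks))) {
      rj <- ranks[j, ]
      leq <- colSums(ranks <= matrix(rj, nrow(ranks), n_spec, byrow = TRUE))
      ap <- ap + leq / rj
    }
    ap / n_relevant
  } else if (objective == "mrr") {
    1 / apply(ranks, 2, min)
  } else {
    as.numeric(apply(ranks, 2, min) <= k)
  }
}

#' @export
print.diish_grid_search <- function(x, ...) {
  cat("<diish_grid_search> ", x$n_combinations, " combinations, best ",
    x$objective_name, " = ", format(x$objective, digits = 4), "\n",
    sep = ""
  )
  print(x$spec)
  invisible(x)
}

#' Split ground truth into development and evaluation targets
#'
#' Draws a seeded uniform sample of target ingredients (without
#' replacement) as the development set for the grid search; the remaining
#' targets form the evaluation set. Dev targets are excluded from
#' evaluation so the tuned combination is scored on unseen targets. Both
#' halves keep the full candidate pool.
#'
#' @param truth A `ground_truth`.
#' @param n_dev Number of development targets (capped at half the targets,
#'   and at the available count).
#' @param seed Integer seed.
#' @return List with `ground_truth` elements `dev` and `eval`.
#' @export
split_dev_targets <- function(truth, n_dev = 100, seed = 1) {
  targets <- sort(unique(truth$pairs$target_id))
  n_dev <- min(n_dev, length(targets) - 1)
  if (n_dev < 1) abort_parameter("too few targets to split a development set")
  dev_targets <- withr::with_seed(seed, sample(targets, n_dev))
  dev_pairs <- truth$pairs[truth$pairs$target_id %in% dev_targets, ]
  eval_pairs <- truth$pairs[!truth$pairs$target_id %in% dev_targets, ]
  list(
    dev = ground_truth(dev_pairs, candidate_pool = truth$candidate_pool),
    eval = ground_truth(eval_pairs, candidate_pool = truth$candidate_pool)
  )
}
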