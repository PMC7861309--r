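#' Train a Poincaré-ball embedding of the class hierarchy
#'
#' Embeds ontology classes in the Poincaré ball by Riemannian SGD with
#' negative sampling over the `subClassOf` edge list (Nickel & Kiela's
#' formulation). Hyperbolic space represents tree-like hierarchies with low
#' distortion, which makes cosine similarity between class vectors a natural
#' hierarchy-aware baseline for ranking substitutes. Defaults follow the
#' common configuration for food-classification embeddings: 50 dimensions,
#' 50 epochs.
#'
#' @param ont A `food_ontology` with at least one `subClassOf` edge.
#' @param dim Embedding dimension.
#' @param epochs Training epochs (a burn-in tenth runs at reduced rate).
#' @param seed Integer seed; training is deterministic given it.
#' @param negatives Negative samples per positive edge.
#' @param lr Learning rate.
#' @return A `hierarchy_embedding` with one vector per class (all strictly
#'   inside the unit ball).
#' @export
train_hierarchy_embedding <- function(ont, dim = 50, epochs = 50, seed = 1,
                                      negatives = 10, lr = 0.1) {
  edges <- ont$edges[ont$edges$relation == "subClassOf", c("child", "parent")]
  if (nrow(edges) == 0) {
    abort_parameter("ontology has no subClassOf edges to train on")
  }
  if (dim <= 0) abort_parameter("embedding dimension must be positive")
  nodes <- sort(unique(c(edges$child, edges$parent)))
  n <- length(nodes)
  ei <- match(edges$child, nodes)
  ej <- match(edges$parent, nodes)

  withr::with_seed(seed, {
    theta <- matrix(stats::runif(n * dim, -1e-3, 1e-3), n, dim)
    burn_in <- max(1L, ceiling(epochs / 10))
    for (epoch in seq_len(epochs)) {
      rate <- if (epoch <= burn_in) lr / 10 else lr
      for (e in sample.int(nrow(edges))) {
        u <- ei[[e]]
        v <- ej[[e]]
        neg <- sample.int(n, negatives, replace = TRUE)
        neg <- neg[neg != u & neg != v]
        cand <- c(v, neg)
        theta <- poincare_step(theta, u, cand, rate)
      }
    }
  })
  rownames(theta) <- nodes
  structure(
    list(dimension = dim, vectors = theta, epochs_trained = epochs,
         seed = seed),
    class = "hierarchy_embedding"
  )
}

# One negative-sampling update: candidate 1 is the positive node.
poincare_step <- function(theta, u, cand, rate) {
  x <- theta[u, ]
  d <- numeric(length(cand))
  gx <- matrix(0, length(cand), ncol(theta))
  gc_ <- matrix(0, length(cand), ncol(theta))
  for (k in seq_along(cand)) {
    y <- theta[cand[[k]], ]
    g <- poincare_dist_grad(x, y)
    d[[k]] <- g$dist
    gx[k, ] <- g$grad_x
    gc_[k, ] <- g$grad_y
  }
  # softmax over negated distances; loss = d_pos + log sum exp(-d)
  w <- exp(-(d - min(d)))
  p <- w / sum(w)
  coef <- -p
  coef[[1]] <- coef[[1]] + 1

  upd <- function(point, grad) {
    scale <- (1 - sum(point^2))^2 / 4
    project_ball(point - rate * scale * grad)
  }
  theta[u, ] <- upd(x, colSums(coef * gx))
  for (k in seq_along(cand)) {
    theta[cand[[k]], ] <- upd(theta[cand[[k]], ], coef[[k]] * gc_[k, ])
  }
  theta
}

poincare_dist_grad <- function(x, y) {
  alpha <- max(1 - sum(x^2), 1e-12)
  beta <- max(1 - sum(y^2), 1e-12)
  sq <- sum((x - y)^2)
  gamma <- 1 + 2 * sq / (alpha * beta)
  dist <- acosh(gamma)
  denom <- sqrt(max(gamma^2 - 1, 1e-12))
  gx <- (4 / (beta * denom)) *
    (((sum(y^2) - 2 * sum(x * y) + 1) / alpha^2) * x - y / alpha)
  gy <- (4 / (alpha * denom)) *
    (((sum(x^2) - 2 * sum(x * y) + 1) / beta^2) * y - x / beta)
  list(dist = dist, grad_x = gx, grad_y = gy)
}

project_ball <- function(x, eps = 1e-5) {
  nrm <- sqrt(sum(x^2))
  if (nrm >= 1) x / nrm * (1 - eps) else x
}

#' @export
print.hierarchy_embedding <- function(x, ...) {
  cat("<hierarchy_embedding> ", nrow(x$vectors), " classes x ", x$dimension,
    " dims, ", x$epochs_trained, " epochs\n",
    sep = ""
  )
  invisible(x)
}

#' Hierarchy-embedding baseline similarity between two ingredients
#'
#' Cosine similarity between the Poincaré vectors of the classes the two
#' ingredients link to. With `ingredients = NULL`, `a` and `b` are taken to
#' be class ids directly.
#'
#' @param emb A `hierarchy_embedding`.
#' @param a,b Ingredient ids (or class ids when `ingredients` is NULL).
#' @param ingredients Optional ingredient table for resolving class links.
#' @return A number in \[-1, 1\].
#' @export
baseline_similarity <- function(emb, a, b, ingredients = NULL) {
  resolve <- function(id) {
    cls <- if (is.null(ingredients)) id else ingredient_class(ingredients, id)
    if (is.na(cls)) {
      abort_lookup(paste0("ingredient '", id, "' has no class link"))
    }
    if (!cls %in% rownames(emb$vectors)) {
      abort_lookup(paste0("class '", cls, "' is not embedded"))
    }
    emb$vectors[cls, ]
  }
  cosine_similarity(resolve(a), resolve(b))
}
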