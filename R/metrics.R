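#' Average precision of one ranking
#'
#' Mean over all relevant items of the precision at their rank; a relevant
#' item absent from the ranking contributes 0 (the divisor is the full
#' relevant-set size, the standard IR convention).
#'
#' @param ranked Character vector of candidate ids in rank order.
#' @param relevant Nonempty character vector of relevant ids.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' average_precision(c("x", "z", "y"), c("x", "y")) # (1/1 + 2/3) / 2
average_precision <- function(ranked, relevant) {
  relevant <- unique(relevant)
  if (length(relevant) == 0) {
    abort_parameter("average precision is undefined for an empty relevant set")
  }
  pos <- sort(match(relevant, ranked))
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0) {
    return(0)
  }
  sum(seq_along(pos) / pos) / length(relevant)
}

#' Reciprocal rank of the first relevant item
#'
#' @inheritParams average_precision
#' @return `1 / rank` of the first relevant item, or 0 if none is ranked.
#' @export
reciprocal_rank <- function(ranked, relevant) {
  pos <- match(relevant, ranked)
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0) {
    return(0)
  }
  1 / min(pos)
}

#' Recall rate at k over a set of targets
#'
#' The fraction of targets for which any relevant candidate appears in the
#' top `k` ranks; nondecreasing in `k`.
#'
#' @param first_ranks Numeric vector with each target's best (lowest)
#'   relevant rank, `Inf` (or NA) when no relevant item is ranked.
#' @param k Rank cutoff.
#' @return A number in \[0, 1\].
#' @export
recall_rate_at_k <- function(first_ranks, k) {
  if (length(first_ranks) == 0) {
    return(0)
  }
  first_ranks[is.na(first_ranks)] <- Inf
  mean(first_ranks <= k)
}

#' Mine substitution pairs from review text
#'
#' Scans free text for simple substitution phrasings and returns
#' direction-normalised `(substitute, target)` phrase pairs: "substitute(d)
#' A for B" and "use(d) A instead of B" yield (A, B), and "replace(d) B with
#' A" yields (A, B). Phrases are lowercased, trimmed, capped at four tokens,
#' and guarded by a stop-span rule: a phrase cannot contain connective or
#' function words (and, with, today, ...), which stops captures at clause
#' boundaries instead of running on through the sentence. Leading
#' articles/determiners are stripped. No knowledge-graph resolution happens
#' here. Text without a pattern yields an empty result.
#'
#' @param text Character vector of review lines.
#' @return A tibble with columns `substitute`, `target`, `line` (index into
#'   `text`), in match order.
#' @export
#' @examples
#' extract_substitutions("I substituted honey for sugar")
extract_substitutions <- function(text) {
  stop_span <- c(
    "and", "or", "but", "so", "then", "because", "since", "when", "while",
    "instead", "with", "for", "as", "in", "on", "to", "at", "it", "its",
    "this", "that", "was", "is", "are", "were", "the", "a", "an", "i", "we",
    "my", "our", "some", "had", "have", "has", "today", "tonight",
    "yesterday", "last", "next", "again", "too", "please", "now", "soon",
    "here", "there", "really", "very", "time", "once"
  )
  tok <- paste0(
    "(?:(?!(?:", paste(stop_span, collapse = "|"), ")\\b)[a-z0-9']+)"
  )
  phrase <- paste0("(", tok, "(?: ", tok, "){0,3})")
  det <- "(?:(?:the|a|an|my|our|some|this|that)\\s+)*"
  patterns <- list(
    list(
      re = paste0(
        "\\bsubstituted?\\s+", det, phrase, "\\s+for\\s+", det, phrase
      ),
      sub = 1L, tgt = 2L
    ),
    list(
      re = paste0(
        "\\breplaced?\\s+", det, phrase, "\\s+with\\s+", det, phrase
      ),
      sub = 2L, tgt = 1L
    ),
    list(
      re = paste0(
        "\\bused?\\s+", det, phrase, "\\s+instead\\s+of\\s+", det, phrase
      ),
      sub = 1L, tgt = 2L
    )
  )
  out <- purrr::map_dfr(seq_along(text), function(line) {
    low <- gsub("[^a-z0-9' ]", " ", tolower(text[[line]]))
    low <- gsub("[[:space:]]+", " ", low)
    purrr::map_dfr(patterns, function(p) {
      m <- stringr::str_match_all(low, p$re)[[1]]
      if (nrow(m) == 0) {
        return(NULL)
      }
      tibble::tibble(
        substitute = clean_phrase(m[, p$sub + 1]),
        target = clean_phrase(m[, p$tgt + 1]),
        line = line
      )
    })
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      substitute = character(), target = character(), line = integer()
    )
  }
  out
}

# lazy-phrase captures can still start with determiners; strip them
clean_phrase <- function(x) {
  x <- trimws(x)
  stop_lead <- c("the", "a", "an", "my", "some", "this", "that", "it")
  vapply(x, function(p) {
    toks <- strsplit(p, " ")[[1]]
    while (length(toks) > 1 && toks[[1]] %in% stop_lead) toks <- toks[-1]
    paste(toks, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Resolve mined phrases against the ingredient table
#'
#' Optional exact-name matching step after [extract_substitutions()]: keeps
#' pairs where both phrases equal a normalised ingredient name.
#'
#' @param pairs Tibble from [extract_substitutions()].
#' @param ingredients Ingredient table.
#' @return Tibble with `target_id`, `substitute_id`.
#' @export
resolve_substitution_phrases <- function(pairs, ingredients) {
  id_of <- stats::setNames(ingredients$ingredient_id, ingredients$name)
  out <- tibble::tibble(
    target_id = unname(id_of[pairs$target]),
    substitute_id = unname(id_of[pairs$substitute])
  )
  out[!is.na(out$target_id) & !is.na(out$substitute_id), ]
}

#' Evaluate a scoring method against ground-truth substitutions
#'
#' For every target in the ground truth, ranks the candidate pool (minus
#' the target, minus hierarchy-filtered candidates when enabled) and
#' aggregates mean average precision, mean reciprocal rank, and recall rate
#' at each requested `k`. Targets the score provider cannot resolve are
#' skipped and counted.
#'
#' @param score_provider Component-score provider function.
#' @param truth A `ground_truth`.
#' @param spec A `diish_spec` used to combine component scores.
#' @param ont,ingredients Needed when `hierarchy_filter` is TRUE.
#' @param hierarchy_filter Apply super/subclass filtering (default TRUE).
#' @param k Integer vector of recall-rate cutoffs.
#' @return A `ranking_report`: `MAP`, `MRR`, `RR_at` (named numeric), the
#'   `per_target` tibble, and `n_skipped`.
#' @export
evaluate_ranking <- function(score_provider, truth,
                             spec = default_diish_spec(),
                             ont = NULL, ingredients = NULL,
                             hierarchy_filter = TRUE, k = c(5, 10)) {
  targets <- sort(unique(truth$pairs$target_id))
  rows <- list()
  n_skipped <- 0L
  for (t in targets) {
    relevant <- truth$pairs$substitute_id[truth$pairs$target_id == t]
    cands <- setdiff(truth$candidate_pool, t)
    ranked <- tryCatch(
      rank_substitutes(
        t, cands, score_provider, spec,
        ont = ont, ingredients = ingredients,
        hierarchy_filter = hierarchy_filter
      ),
      substkg_lookup_error = function(e) NULL
    )
    if (is.null(ranked)) {
      n_skipped <- n_skipped + 1L
      next
    }
    ids <- ranked$candidate_id
    pos <- match(relevant, ids)
    pos <- pos[!is.na(pos)]
    rows[[t]] <- tibble::tibble(
      target_id = t,
      n_relevant = length(relevant),
      ap = average_precision(ids, relevant),
      rr = reciprocal_rank(ids, relevant),
      first_rank = if (length(pos) == 0) Inf else min(pos)
    )
  }
  if (n_skipped > 0) {
    rlang::warn(paste0(n_skipped, " target(s) skipped: unresolvable"))
  }
  per_target <- dplyr::bind_rows(rows)
  if (nrow(per_target) == 0) {
    abort_validation("no evaluable targets in the ground truth")
  }
  rr_at <- vapply(k, function(kk) {
    recall_rate_at_k(per_target$first_rank, kk)
  }, numeric(1))
  structure(
    list(
      MAP = mean(per_target$ap),
      MRR = mean(per_target$rr),
      RR_at = stats::setNames(rr_at, paste0("rr@", k)),
      per_target = per_target,
      n_skipped = n_skipped
    ),
    class = "ranking_report"
  )
}

#' @export
print.ranking_report <- function(x, ...) {
  cat("<ranking_report> ", nrow(x$per_target), " targets\n", sep = "")
  cat("  MAP: ", format(x$MAP, digits = 4),
    "  MRR: ", format(x$MRR, digits = 4), "\n",
    sep = ""
  )
  for (n in names(x$RR_at)) {
    cat("  ", n, ": ", format(x$RR_at[[n]], digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a ranking report into per-target rows
#'
#' @param x A `ranking_report`.
#' @param ... Unused.
#' @return The per-target tibble (`target_id`, `n_relevant`, `ap`, `rr`,
#'   `first_rank`).
#' @exportS3Method generics::tidy
tidy.ranking_report <- function(x, ...) {
  x$per_target
}

#' One-row summary of a ranking report
#'
#' @param x A `ranking_report`.
#' @param ... Unused.
#' @return A one-row tibble with `map`, `mrr`, one `rr_at_*` column per
#'   cutoff, `n_targets` and `n_skipped`.
#' @exportS3Method generics::glance
glance.ranking_report <- function(x, ...) {
  out <- tibble::tibble(
    map = x$MAP, mrr = x$MRR,
    n_targets = nrow(x$per_target), n_skipped = x$n_skipped
  )
  for (n in names(x$RR_at)) {
    out[[gsub("@", "_at_", n)]] <- x$RR_at[[n]]
  }
  out
}
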