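---
title: "Ranking ingredient substitutions over a food knowledge graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking ingredient substitutions over a food knowledge graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

substkg ranks plausible ingredient substitutions for a recipe under
personal dietary constraints. It operates over a small food knowledge
graph: a class ontology (a DAG under `subClassOf` and `derivesFrom`
relations), an ingredient table linking ingredients to classes and to
per-100 g nutrition records, and a recipe corpus. This vignette explains
the model, its tunable parameters, the numerical conventions, and what the
bundled synthetic data generator does and does not emulate.

## The substitutability heuristic

Whether one ingredient can stand in for another is not observable from any
single signal, so the package combines four pairwise scores, each capturing
a different sense of "plays the same role":

* **W** — cosine similarity between ingredient-name embeddings trained on
  the package's own recipe corpus (names plus instruction text). Captures
  corpus-specific usage: ingredients handled the same way end up close.
* **S** — the same cosine under a *general-language* embedding provided as
  a static vector table. Captures broad lexical similarity that the small
  recipe corpus cannot.
* **D** — cosine similarity between subclass-expanded recipe co-occurrence
  count vectors. `T[j, i]` counts recipes where `j` appears with `i` or
  with anything at-or-below `i`'s class; two ingredients with similar rows
  keep the same company.
* **P** — cosine similarity between PPMI-weighted recipe-context vectors,
  computed at the class level. The context of an ingredient in a recipe is
  the set of the other members' classes; the focal class is also
  generalised to its `subClassOf` ancestors when counting.

The combined score (DIISH, the diet-improvement ingredient substitutability
heuristic) is a weighted power sum

$$\mathrm{DIISH}_{a,b} \;=\; c_W W_{a,b}^{p_W} + c_S S_{a,b}^{p_S}
 + c_D D_{a,b}^{p_D} + c_P P_{a,b}^{p_P},$$

with coefficients drawn from $\{0.5, 1, 2, 4\}$ and powers from
$\{\tfrac14, \tfrac12, 1, 2\}$. Since every component is bounded by 1, a
fractional power inflates a metric's influence and a square deflates it.
`grid_search_diish()` enumerates all $16^4 = 65{,}536$ combinations on a
seeded development split of the ground truth and returns the argmax under
MAP (or MRR / RR\@k; the objective is a configuration choice, with MAP the
default). Component scores are computed once per target and reused across
all combinations, which keeps the full enumeration in the seconds range at
the bundled problem sizes.

The shipped default preset is
$W + \tfrac12 S + \tfrac12 D^{1/4} + 2P$. As conventionally typeset the
heuristic's D exponent is ambiguous (it can be read as
$D^4$ or $D^{1/4}$); we default to $1/4$ because the tuning power grid
contains $1/4$ but not $4$, and ship the other reading as
`alt_diish_spec()`. Nothing downstream depends on the choice: every
evaluation and the acceptance checks pass specs explicitly.

## Filtering

Two filters sit in front of the ranking:

* **Hierarchy filter.** Candidates whose class lies on a `subClassOf` path
  through the target's class (ancestors, descendants, or the same class)
  are removed, as is the target itself: a specific potato variety is not a
  useful substitute for "potatoes". `derivesFrom` deliberately does not
  participate here — a derived product (bacon vs. pork) can be a
  legitimate substitute direction — while it *does* participate in
  restriction checks below. The relation set is therefore an explicit
  argument of the closure functions.
* **Healthy-candidate filter.** For a nutrient-reduction goal, a candidate
  must contain *strictly* less of the nutrient per 100 g than the target
  (per-100 g, not per-recipe-quantity, matching how substitution tables are
  presented) and must not violate any class restriction. Restriction
  checking walks ancestor paths over both `subClassOf` and `derivesFrom`,
  so prohibiting "meat" also prohibits anything deriving from it.

## Nutrition accounting

`recipe_nutrients()` converts each quantified ingredient to grams and
scales its per-100 g nutrient amounts. Gram resolution order: recognised
mass units (g, kg, mg, oz, lb) convert directly; otherwise the unit text is
substring-matched case-insensitively against the record's common-unit
descriptions ("1 tsp" → 4.3 g); with no match, or no unit at all ("2
lemons"), the *first* common unit is the default weight. Volume units
without a matching description are not density-converted — there is no
density table — and fall through to the same default. Unquantified
("—") rows contribute zero. Totals are conserved exactly (the recipe
total is the componentwise sum of per-ingredient totals); display rounding
is one decimal, internal arithmetic is unrounded.

## Numerical conventions

* **Cosines.** A zero vector yields cosine 0, never NaN. D and P are in
  $[0,1]$ because their vectors are nonnegative; W and S live in $[-1,1]$.
* **Clamping.** Before a *non-integer* power, negative component values are
  clamped to 0 so fractional exponents stay real; integer powers use the
  raw value. With this convention `combine_scores()` is monotone
  nondecreasing in every component whenever coefficients are positive.
* **PPMI.** Two normalisations are available:
  `max(0, log(F_ic * max(F_i, F_c) / (F_i F_c)))` (default) and the
  textbook corpus-total form `max(0, log(F_ic * N / (F_i F_c)))` with `N`
  the number of base (class, context) counting events. The compact way
  this weight is usually written down does not parse uniquely, so both
  readings are shipped behind `normalizer = c("max", "total")` and neither is asserted
  as the canonical one. Note the max-normalised form can zero an entire
  PPMI row (every pair score ≤ 0), in which case the zero-vector cosine
  convention applies. Logs are natural; the base cancels in the cosine.
* **Ties.** Rankings order by score descending with ties broken by
  ingredient id ascending, making every ranking deterministic. Grid-search
  ties resolve to the first combination in enumeration order (first grid
  column varying fastest).
* **Name normalisation.** All joins use lowercased, trimmed,
  whitespace-collapsed names; raw spellings are kept for display. Multi-word
  names embed as the unweighted mean of their in-vocabulary token vectors;
  a fully out-of-vocabulary name embeds to the zero vector.
* **AP divisor.** Average precision divides by the full relevant-set size,
  so a relevant substitute missing from the ranking (for instance, removed
  by a filter) is penalised rather than ignored. This is the standard IR
  convention.

## Embedding choices

The corpus embedding is computed by truncated SVD of the windowed
token-token PPMI matrix (window 5, symmetric), taking
$U_k\,\mathrm{diag}(\sqrt{d_k})$ as token vectors with per-column sign
fixing. This is the implicit matrix-factorisation objective of skip-gram
with negative sampling, and it has a property we value in tests: training
is exactly reproducible for a fixed corpus, with no dependence on thread
scheduling or update order. The seed is recorded in the model metadata.

The general-language provider S is deliberately pluggable: any vector table
in the word2vec text format (`read_word_vectors()`) works, because a
pretrained model is an artifact, not a method. The synthetic bundle ships
its own family-correlated synthetic table so the full pipeline runs without
downloads.

The hierarchy-embedding baseline places ontology classes in the Poincaré
ball by Riemannian SGD with negative sampling over the `subClassOf` edge
list (50 dimensions, 50 epochs by default, with a burn-in tenth at a
reduced learning rate). Hyperbolic geometry represents tree-like structure
with low distortion, making class-vector cosine a natural hierarchy-aware
ranking baseline to compare DIISH against.

## The synthetic data generator

`generate_food_kg()` produces every input table from a seed, with planted
structure chosen to emulate exactly the statistical assumptions the scores
rely on:

* **Families of substitutable ingredients** sit on sibling leaf classes
  under a per-family parent class (so ground-truth pairs are never
  super/subclass-related and survive the hierarchy filter).
* **Recipes are sampled from family-slot templates**: a template fixes
  which families co-occur, and each recipe drawing it picks one member per
  slot uniformly. Template reuse makes recipe contexts repeat, which is
  what gives family mates overlapping co-occurrence rows (D) and context
  supports (P). One extra ingredient shares a leaf class with a family
  member to exercise the class-collapse behaviour of P.
* **Nutrition** is drawn from family-level means with multiplicative
  lognormal noise (σ = 0.12), keeping amounts positive; high-carbohydrate
  families sit at 20 g/100 g against 5 g/100 g elsewhere, a ≥ 2× separation
  so strict-inequality filtering decides on margins, not knife edges.
* **Reviews** embed each planted pair in one of the three substitution
  phrasings the miner knows, plus keyword-free distractor lines; the
  generator and the extractor share the pattern inventory by construction,
  which is why near-total recovery is a generator invariant rather than an
  empirical claim about real review text.

Default sizes — 8 families × 4 members, 400 recipes of 4–8 slots, 10%
pantry-staple noise — are small enough that the complete test suite and the
full 65,536-combination grid search run in well under a minute, while still
leaving ~100 directed truth pairs and ~33 ranking targets.

What the generator does *not* emulate: linking errors between ingredients
and classes (a major error source on real knowledge graphs), polysemous
ingredient names, quantity-dependent substitutability, and the long-tailed
ingredient frequency distribution of real corpora. Passing tests on the
fixture therefore demonstrate correctness of the machinery and the
direction of effects (e.g. filtering does not hurt ranking quality), not
absolute performance on real data. In particular the hierarchy-embedding
baseline is *artificially strong* here, because the synthetic ontology
aligns perfectly with the planted families — an alignment real food
ontologies do not have.

## Development/evaluation protocol

`split_dev_targets()` draws a seeded uniform sample of ranking targets
without replacement as the development set for the grid search; those
targets are excluded from the final evaluation so the tuned combination is
always scored on unseen targets. The bundled acceptance computation uses 8
development targets out of ~33 — proportionally the same role the
100-target development split plays on a corpus of a thousand-odd
ingredients.

## Known limitations

* Review mining is regular-expression based with a stop-span guard (a
  phrase may not contain connective/function words and is capped at four
  tokens). Phrases like "cream of tartar" are truncated at "of"; resolving
  mined phrases to ingredients is exact-name matching only.
* `to_grams()` trusts the first common unit as a default; for ingredients
  whose common units differ wildly in scale this can be badly wrong, which
  mirrors how sparse measure descriptions behave on real data.
* One-to-many substitutions, quantity rescaling of the substitute, and
  instruction rewriting are out of scope.
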