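{"recipe_id":"roast_potatoes","name":"lemon and red onion roasted potatoes","ingredients":[{"ingredient_id":"black pepper"},{"ingredient_id":"coarse sea salt"},{"ingredient_id":"olive oil","amount":6,"unit":"tsp"},{"ingredient_id":"lemon","amount":2},{"ingredient_id":"red onion","amount":3},{"ingredient_id":"potatoes","amount":1,"unit":"kg"}],"servings":4,"instructions":"toss the potatoes with olive oil lemon and red onion then roast"}
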