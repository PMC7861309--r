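nutrition_id	description	grams
n_pot	1 cup	150
n_lem	1 fruit	58
n_oni	1 onion	160
n_oil	1 tsp	4.333333333333333
n_oil	1 tbsp	13
n_pep	1 tsp	2.3
n_salt	1 tsp	6
n_tur	1 cup	130
n_cau	1 cup	107
n_squ	1 cup	113
n_but	1 cup	140
n_zuc	1 cup	124
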