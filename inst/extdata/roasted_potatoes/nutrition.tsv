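nutrition_id	nutrient	amount	unit
n_pot	carbohydrate	17.5	g
n_lem	carbohydrate	9.3	g
n_oni	carbohydrate	9.3	g
n_oil	carbohydrate	0	g
n_pep	carbohydrate	0	g
n_salt	carbohydrate	0	g
n_tur	carbohydrate	6.4	g
n_cau	carbohydrate	5	g
n_squ	carbohydrate	6.9	g
n_but	carbohydrate	11.7	g
n_zuc	carbohydrate	3.1	g
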