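ingredient_id	name	class_id	nutrition_id
potatoes	Potatoes	potato class	n_pot
lemon	Lemon	lemon class	n_lem
red onion	Red Onion	red onion class	n_oni
olive oil	Olive Oil	olive oil class	n_oil
black pepper	Black Pepper	pepper class	n_pep
coarse sea salt	Coarse Sea Salt	salt class	n_salt
turnip	Turnip	turnip class	n_tur
cauliflower	Cauliflower	cauliflower class	n_cau
squash	Squash	squash class	n_squ
butternut squash	Butternut Squash	butternut squash class	n_but
zucchini	Zucchini	zucchini class	n_zuc
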