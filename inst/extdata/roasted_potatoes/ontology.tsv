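child	relation	parent
potato class	subClassOf	vegetable
lemon class	subClassOf	fruit
red onion class	subClassOf	vegetable
olive oil class	subClassOf	fat
pepper class	subClassOf	spice
salt class	subClassOf	spice
turnip class	subClassOf	vegetable
cauliflower class	subClassOf	vegetable
squash class	subClassOf	vegetable
zucchini class	subClassOf	vegetable
butternut squash class	subClassOf	vegetable
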