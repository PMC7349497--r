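component,grams_served
calories,620
carbohydrate,58
protein,34
sugar,12
fat,22
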