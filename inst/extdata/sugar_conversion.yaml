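# Converting factors: fraction of an ingredient's recipe weight counted as
# equivalent (free) sugar. White sugar 1.0 and honey 0.8 are the anchoring
# values of the systematic added-sugar estimation method; syrup and
# fruit-juice-concentrate factors are configurable defaults. Ingredients
# absent from this table contribute no free sugar.
converting_factors:
  white_sugar: 1.0
  honey: 0.8
  syrup: 0.8
  fruit_juice_concentrate: 1.0
  glucose_syrup: 1.0
  brown_sugar: 0.97
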