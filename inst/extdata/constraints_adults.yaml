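# Nutritional constraint set for the individual diet models: 33 nutrient
# rows (macronutrient energy shares, fiber, moderation maxima, the
# conditional free-sugar rule and 22 micronutrient minima) plus structural
# rows (iso-energy, total diet weight, total diet cost; acceptability maxima
# per food and sub-category are data-driven and added at model build time).
# Bounds are a reconstruction from French adult dietary reference values.
#
# kind: nutrient_min | nutrient_max | free_sugar_conditional
# basis: absolute_per_day | percent_energy (percent-energy rows are rewritten
#        as linear rows using the individual's fixed energy target;
#        grams <-> energy for sugars uses 4 kcal/g, fat rows 9 kcal/g,
#        protein 4 kcal/g)
nutritional_constraints:
  - {id: protein_min,     kind: nutrient_min, nutrient: protein,     bound: 10,   basis: percent_energy}
  - {id: protein_max,     kind: nutrient_max, nutrient: protein,     bound: 20,   basis: percent_energy}
  - {id: fat_min,         kind: nutrient_min, nutrient: fat,         bound: 30,   basis: percent_energy}
  - {id: fat_max,         kind: nutrient_max, nutrient: fat,         bound: 40,   basis: percent_energy}
  - {id: carb_min,        kind: nutrient_min, nutrient: carb,        bound: 45,   basis: percent_energy}
  - {id: carb_max,        kind: nutrient_max, nutrient: carb,        bound: 60,   basis: percent_energy}
  - {id: fiber_min,       kind: nutrient_min, nutrient: fiber,       bound: 25,   basis: absolute_per_day}
  - {id: sfa_max,         kind: nutrient_max, nutrient: sfa,         bound: 12,   basis: percent_energy}
  - {id: cholesterol_max, kind: nutrient_max, nutrient: cholesterol, bound: 300,  basis: absolute_per_day}
  - {id: sodium_max,      kind: nutrient_max, nutrient: sodium,      bound: 3150, basis: absolute_per_day}
  # 10% maximum energy from free sugars when the observed share exceeds 10%,
  # otherwise "no increase" above the observed amount
  - {id: free_sugars_max, kind: free_sugar_conditional, nutrient: free_sugars, bound: 10, basis: percent_energy}
  - {id: vit_a_min,      kind: nutrient_min, nutrient: vit_a,      bound: 700,  basis: absolute_per_day}
  - {id: vit_d_min,      kind: nutrient_min, nutrient: vit_d,      bound: 5,    basis: absolute_per_day}
  - {id: vit_e_min,      kind: nutrient_min, nutrient: vit_e,      bound: 12,   basis: absolute_per_day}
  - {id: vit_k_min,      kind: nutrient_min, nutrient: vit_k,      bound: 45,   basis: absolute_per_day}
  - {id: vit_c_min,      kind: nutrient_min, nutrient: vit_c,      bound: 110,  basis: absolute_per_day}
  - {id: b1_min,         kind: nutrient_min, nutrient: b1,         bound: 1.2,  basis: absolute_per_day}
  - {id: b2_min,         kind: nutrient_min, nutrient: b2,         bound: 1.55, basis: absolute_per_day}
  - {id: b3_min,         kind: nutrient_min, nutrient: b3,         bound: 13,   basis: absolute_per_day}
  - {id: b5_min,         kind: nutrient_min, nutrient: b5,         bound: 5,    basis: absolute_per_day}
  - {id: b6_min,         kind: nutrient_min, nutrient: b6,         bound: 1.65, basis: absolute_per_day}
  - {id: b9_min,         kind: nutrient_min, nutrient: b9,         bound: 315,  basis: absolute_per_day}
  - {id: b12_min,        kind: nutrient_min, nutrient: b12,        bound: 2.4,  basis: absolute_per_day}
  - {id: calcium_min,    kind: nutrient_min, nutrient: calcium,    bound: 900,  basis: absolute_per_day}
  - {id: magnesium_min,  kind: nutrient_min, nutrient: magnesium,  bound: 390,  basis: absolute_per_day}
  - {id: potassium_min,  kind: nutrient_min, nutrient: potassium,  bound: 3100, basis: absolute_per_day}
  - {id: iron_min,       kind: nutrient_min, nutrient: iron,       bound: 12.5, basis: absolute_per_day}
  - {id: zinc_min,       kind: nutrient_min, nutrient: zinc,       bound: 11,   basis: absolute_per_day}
  - {id: copper_min,     kind: nutrient_min, nutrient: copper,     bound: 1.7,  basis: absolute_per_day}
  - {id: iodine_min,     kind: nutrient_min, nutrient: iodine,     bound: 150,  basis: absolute_per_day}
  - {id: selenium_min,   kind: nutrient_min, nutrient: selenium,   bound: 55,   basis: absolute_per_day}
  - {id: phosphorus_min, kind: nutrient_min, nutrient: phosphorus, bound: 750,  basis: absolute_per_day}
  - {id: manganese_min,  kind: nutrient_min, nutrient: manganese,  bound: 2.5,  basis: absolute_per_day}

structural_constraints:
  # iso-energy at the observed non-alcoholic energy intake
  energy_equality: true
  # total diet weight (energy-free drinks excluded) and total diet cost,
  # as multiples of the observed values
  total_weight_multiplier: 1.3
  total_cost_multiplier: 1.1
  # acceptability maxima: quantile of consumption among consumers, per food
  # and per leaf sub-category, computed on the loaded population
  acceptability_quantile: 0.95
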