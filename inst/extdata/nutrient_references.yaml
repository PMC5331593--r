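# Nutrient reference values for French adults (single sex-averaged table;
# a reconstruction from French adult dietary reference values, labelled as
# such — the package treats this file, not a hard-coded list, as the
# contract).
#
# role: adequacy (has rni used by MAR, ear + cv used by PANDiet) or
#       moderation (has max_value, basis absolute or percent_energy).
# Units: g/day for protein and fiber, mg/day unless noted; vit_a/vit_d/vit_k,
# b9, b12, iodine, selenium in ug/day; sfa and free_sugars moderation
# references as % of energy.
#
# mar: true        -> one of the 23 MAR nutrients
# pandiet: true    -> one of the 25 PANDiet nutrients (22 adequacy + 3 moderation)
nutrients:
  - {id: protein,    role: adequacy, rni: 55,   ear: 46,   cv: 0.125, unit: g,  mar: true, pandiet: true}
  - {id: fiber,      role: adequacy, rni: 25,   ear: 20,   cv: 0.15,  unit: g,  mar: true, pandiet: false}
  - {id: vit_a,      role: adequacy, rni: 700,  ear: 530,  cv: 0.15,  unit: ug, mar: true, pandiet: true}
  - {id: vit_d,      role: adequacy, rni: 5,    ear: 4,    cv: 0.25,  unit: ug, mar: true, pandiet: true}
  - {id: vit_e,      role: adequacy, rni: 12,   ear: 9,    cv: 0.15,  unit: mg, mar: true, pandiet: true}
  - {id: vit_c,      role: adequacy, rni: 110,  ear: 85,   cv: 0.15,  unit: mg, mar: true, pandiet: true}
  - {id: b1,         role: adequacy, rni: 1.2,  ear: 0.95, cv: 0.15,  unit: mg, mar: true, pandiet: true}
  - {id: b2,         role: adequacy, rni: 1.55, ear: 1.2,  cv: 0.15,  unit: mg, mar: true, pandiet: true}
  - {id: b3,         role: adequacy, rni: 13,   ear: 10.3, cv: 0.15,  unit: mg, mar: true, pandiet: true}
  - {id: b5,         role: adequacy, rni: 5,    ear: 4,    cv: 0.15,  unit: mg, mar: true, pandiet: true}
  - {id: b6,         role: adequacy, rni: 1.65, ear: 1.3,  cv: 0.15,  unit: mg, mar: true, pandiet: true}
  - {id: b9,         role: adequacy, rni: 315,  ear: 250,  cv: 0.15,  unit: ug, mar: true, pandiet: true}
  - {id: b12,        role: adequacy, rni: 2.4,  ear: 2.0,  cv: 0.15,  unit: ug, mar: true, pandiet: true}
  - {id: calcium,    role: adequacy, rni: 900,  ear: 750,  cv: 0.125, unit: mg, mar: true, pandiet: true}
  - {id: magnesium,  role: adequacy, rni: 390,  ear: 310,  cv: 0.15,  unit: mg, mar: true, pandiet: true}
  - {id: potassium,  role: adequacy, rni: 3100, ear: 2600, cv: 0.15,  unit: mg, mar: true, pandiet: true}
  - {id: iron,       role: adequacy, rni: 12.5, ear: 9,    cv: 0.20,  unit: mg, mar: true, pandiet: true}
  - {id: zinc,       role: adequacy, rni: 11,   ear: 8.5,  cv: 0.15,  unit: mg, mar: true, pandiet: true}
  - {id: copper,     role: adequacy, rni: 1.7,  ear: 1.2,  cv: 0.15,  unit: mg, mar: true, pandiet: true}
  - {id: iodine,     role: adequacy, rni: 150,  ear: 107,  cv: 0.20,  unit: ug, mar: true, pandiet: true}
  - {id: selenium,   role: adequacy, rni: 55,   ear: 45,   cv: 0.15,  unit: ug, mar: true, pandiet: true}
  - {id: phosphorus, role: adequacy, rni: 750,  ear: 580,  cv: 0.15,  unit: mg, mar: true, pandiet: true}
  - {id: manganese,  role: adequacy, rni: 2.5,  ear: 2.0,  cv: 0.15,  unit: mg, mar: true, pandiet: true}
  - {id: vit_k,      role: adequacy, rni: 45,   ear: 35,   cv: 0.15,  unit: ug, mar: false, pandiet: false}
  - {id: sodium,      role: moderation, max_value: 3150, basis: absolute,       cv: 0.15, unit: mg, mer: true, pandiet: true}
  - {id: sfa,         role: moderation, max_value: 12,   basis: percent_energy, cv: 0.15, unit: g,  mer: true, pandiet: true}
  - {id: free_sugars, role: moderation, max_value: 10,   basis: percent_energy, cv: 0.15, unit: g,  mer: true, pandiet: true}
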