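[
  {"pattern": "F63*", "category": "disruptive_impulse_conduct"},
  {"pattern": "F91*", "category": "disruptive_impulse_conduct"},
  {"pattern": "F64*", "category": "gender_dysphoria"},
  {"pattern": "F90*", "category": "adhd"},
  {"pattern": "F2*",  "category": "schizophrenia_spectrum"},
  {"pattern": "F30*", "category": "bipolar"},
  {"pattern": "F31*", "category": "bipolar"},
  {"pattern": "F32*", "category": "depressive"},
  {"pattern": "F33*", "category": "depressive"},
  {"pattern": "F34*", "category": "depressive"},
  {"pattern": "F40*", "category": "anxiety"},
  {"pattern": "F41*", "category": "anxiety"},
  {"pattern": "F42*", "category": "obsessive_compulsive"},
  {"pattern": "F43*", "category": "trauma_stressor"},
  {"pattern": "F44*", "category": "dissociative"},
  {"pattern": "F50*", "category": "feeding_eating"},
  {"pattern": "F6*",  "category": "personality"}
]
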