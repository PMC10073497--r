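{
  "name": "Ti6Al4V ELI, ASTM F3001-14 minima",
  "ultimate_strength_MPa": 860,
  "yield_strength_MPa": 795,
  "elastic_modulus_GPa": 110,
  "elongation": 0.10,
  "poisson_ratio": 0.34
}
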