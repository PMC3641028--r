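{
  "name": "sbw25_core",
  "n_metabolites": 70,
  "n_reactions": 77,
  "n_exchange": 12,
  "subsystems": {
    "acetate metabolism": 2,
    "alginate biosynthesis": 6,
    "biomass": 1,
    "entner-doudoroff": 2,
    "exchange": 12,
    "fructose utilization": 2,
    "glycerol utilization": 3,
    "glycolysis/gluconeogenesis": 10,
    "maintenance": 1,
    "nadph cycle": 4,
    "nucleotide interconversion": 2,
    "pentose phosphate": 8,
    "phosphate metabolism": 1,
    "pyruvate metabolism": 3,
    "respiration": 2,
    "respiration:cytochrome-c": 1,
    "respiration:ubiquinol": 2,
    "tca cycle": 8,
    "transport": 7
  }
}
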