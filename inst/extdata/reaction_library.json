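[
  {
    "id": "T3.eq2",
    "equation": "S0 + O2 + H2O -> SO3^2- + 2 H+",
    "reversible": false,
    "source": "table3",
    "catalysts": [
      "Hdr",
      "Sdo",
      "Sor"
    ],
    "abiotic_possible": false,
    "free_species": []
  },
  {
    "id": "T3.eq3",
    "equation": "SO3^2- + 1/2 O2 -> SO4^2-",
    "reversible": false,
    "source": "table3",
    "catalysts": [],
    "abiotic_possible": true,
    "free_species": []
  },
  {
    "id": "T3.eq4f",
    "equation": "S0 + SO3^2- -> S2O3^2-",
    "reversible": false,
    "source": "table3",
    "catalysts": [
      "Rhd",
      "Sox"
    ],
    "abiotic_possible": false,
    "free_species": []
  },
  {
    "id": "T3.eq4r",
    "equation": "S2O3^2- -> S0 + SO3^2-",
    "reversible": false,
    "source": "table3",
    "catalysts": [
      "Rhd",
      "Sox"
    ],
    "abiotic_possible": true,
    "free_species": []
  },
  {
    "id": "T3.eq5",
    "equation": "2 S2O3^2- + 1/2 O2 + 2 H+ -> S4O6^2- + H2O",
    "reversible": false,
    "source": "table3",
    "catalysts": [
      "DoxD",
      "TetH"
    ],
    "abiotic_possible": false,
    "free_species": []
  },
  {
    "id": "T3.eq6",
    "equation": "S4O6^2- + 7/2 O2 + 3 H2O -> 4 SO4^2- + 6 H+",
    "reversible": false,
    "source": "table3",
    "catalysts": [
      "TetH"
    ],
    "abiotic_possible": false,
    "free_species": []
  },
  {
    "id": "T3.eq9",
    "equation": "SO3^2- + H2O -> SO4^2- + 2 H+",
    "reversible": false,
    "source": "table3",
    "catalysts": [
      "Aps",
      "Paps"
    ],
    "abiotic_possible": false,
    "free_species": [
      "e-"
    ]
  },
  {
    "id": "T3.eq10",
    "equation": "S4O6^2- + H2O -> S3O3^2- + SO4^2- + 2 H+",
    "reversible": false,
    "source": "table3",
    "catalysts": [
      "TetH"
    ],
    "abiotic_possible": true,
    "free_species": []
  },
  {
    "id": "T3.eq11",
    "equation": "4 S3O3^2- -> 8 S0 + 4 SO3^2-",
    "reversible": false,
    "source": "table3",
    "catalysts": [],
    "abiotic_possible": true,
    "free_species": []
  },
  {
    "id": "F1.sqr",
    "equation": "S^2- + 1/2 O2 + 2 H+ -> S0 + H2O",
    "reversible": false,
    "source": "fig1_derived",
    "catalysts": [
      "Sqr"
    ],
    "abiotic_possible": false,
    "free_species": []
  },
  {
    "id": "F1.sox",
    "equation": "S2O3^2- + 1/2 O2 -> S0 + SO4^2-",
    "reversible": false,
    "source": "fig1_derived",
    "catalysts": [
      "Sox"
    ],
    "abiotic_possible": false,
    "free_species": []
  }
]
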