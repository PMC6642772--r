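{
  "comment": "Candidate redox reactions for partial nitrification and sulfur-based autotrophic denitrification. stoichiometry: signed coefficients (products positive); electrons: mol e- transferred per reaction as written; dg0_kj: standard Gibbs free energy, kJ per reaction as written; quotient: species exponents of the reaction quotient Q (solids and water excluded, unit activity).",
  "reactions": [
    {
      "id": "i",
      "process": "nitrification",
      "label": "NH4+ + 3/2 O2 -> NO2- + 2 H+ + H2O",
      "stoichiometry": {"NH4+": -1, "O2": -1.5, "NO2-": 1, "H+": 2, "H2O": 1},
      "electrons": 6,
      "dg0_kj": -273.0,
      "quotient": {"NO2-": 1, "H+": 2, "NH4+": -1, "O2": -1.5}
    },
    {
      "id": "ii",
      "process": "nitrification",
      "label": "2 NH4+ + 2 O2 -> N2O + 2 H+ + 3 H2O",
      "stoichiometry": {"NH4+": -2, "O2": -2, "N2O": 1, "H+": 2, "H2O": 3},
      "electrons": 8,
      "dg0_kj": -526.6,
      "quotient": {"N2O": 1, "H+": 2, "NH4+": -2, "O2": -2}
    },
    {
      "id": "iii",
      "process": "denitrification",
      "label": "5 HS- + 2 NO3- + 7 H+ -> 5 S0 + N2 + 6 H2O",
      "stoichiometry": {"HS-": -5, "NO3-": -2, "H+": -7, "S0": 5, "N2": 1, "H2O": 6},
      "electrons": 10,
      "dg0_kj": -990.1,
      "quotient": {"N2": 1, "HS-": -5, "NO3-": -2, "H+": -7}
    },
    {
      "id": "iv",
      "process": "denitrification",
      "label": "5 HS- + 8 NO3- + 3 H+ -> 5 SO4-2 + 4 N2 + 4 H2O",
      "stoichiometry": {"HS-": -5, "NO3-": -8, "H+": -3, "SO4-2": 5, "N2": 4, "H2O": 4},
      "electrons": 40,
      "dg0_kj": -3726.9,
      "quotient": {"SO4-2": 5, "N2": 4, "HS-": -5, "NO3-": -8, "H+": -3}
    },
    {
      "id": "v",
      "process": "denitrification",
      "label": "HS- + NO3- + H+ -> S0 + NO2- + H2O",
      "stoichiometry": {"HS-": -1, "NO3-": -1, "H+": -1, "S0": 1, "NO2-": 1, "H2O": 1},
      "electrons": 2,
      "dg0_kj": -136.6,
      "quotient": {"NO2-": 1, "HS-": -1, "NO3-": -1, "H+": -1}
    },
    {
      "id": "vi",
      "process": "denitrification",
      "label": "HS- + 4 NO3- -> SO4-2 + H+ + 4 NO2-",
      "stoichiometry": {"HS-": -1, "NO3-": -4, "SO4-2": 1, "H+": 1, "NO2-": 4},
      "electrons": 8,
      "dg0_kj": -499.7,
      "quotient": {"SO4-2": 1, "H+": 1, "NO2-": 4, "HS-": -1, "NO3-": -4}
    },
    {
      "id": "vii",
      "process": "denitrification",
      "label": "5 S0 + 6 NO3- + 2 H2O -> 5 SO4-2 + 4 H+ + 3 N2",
      "stoichiometry": {"S0": -5, "NO3-": -6, "H2O": -2, "SO4-2": 5, "H+": 4, "N2": 3},
      "electrons": 30,
      "dg0_kj": -2736.8,
      "quotient": {"SO4-2": 5, "H+": 4, "N2": 3, "NO3-": -6}
    },
    {
      "id": "viii",
      "process": "denitrification",
      "label": "S0 + 3 NO3- + H2O -> SO4-2 + 2 H+ + 3 NO2-",
      "stoichiometry": {"S0": -1, "NO3-": -3, "H2O": -1, "SO4-2": 1, "H+": 2, "NO2-": 3},
      "electrons": 6,
      "dg0_kj": -414.9,
      "quotient": {"SO4-2": 1, "H+": 2, "NO2-": 3, "NO3-": -3}
    }
  ]
}
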