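{
  "id": "toy_s101_p3_a2_h1",
  "metabolites": [
    {
      "id": "N1_1",
      "name": "N1_1",
      "compartment": "c",
      "formula": "C6H12O6"
    },
    {
      "id": "N1_2",
      "name": "N1_2",
      "compartment": "c",
      "formula": "C2H4O2"
    },
    {
      "id": "N2_1",
      "name": "N2_1",
      "compartment": "c",
      "formula": "C3H7NO2"
    },
    {
      "id": "N2_2",
      "name": "N2_2",
      "compartment": "c",
      "formula": "C5H5N5"
    },
    {
      "id": "N3_1",
      "name": "N3_1",
      "compartment": "c",
      "formula": "H3PO4"
    },
    {
      "id": "N3_2",
      "name": "N3_2",
      "compartment": "c",
      "formula": "CH4N2O"
    },
    {
      "id": "H1",
      "name": "H1",
      "compartment": "c",
      "formula": "C12H22O11"
    },
    {
      "id": "P1",
      "name": "P1",
      "compartment": "c"
    },
    {
      "id": "P2",
      "name": "P2",
      "compartment": "c"
    },
    {
      "id": "P3",
      "name": "P3",
      "compartment": "c"
    }
  ],
  "reactions": [
    {
      "id": "EX_N1_1",
      "name": "EX_N1_1",
      "metabolites": {
        "N1_1": -1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "EX_N1_2",
      "name": "EX_N1_2",
      "metabolites": {
        "N1_2": -1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "EX_N2_1",
      "name": "EX_N2_1",
      "metabolites": {
        "N2_1": -1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "EX_N2_2",
      "name": "EX_N2_2",
      "metabolites": {
        "N2_2": -1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "EX_N3_1",
      "name": "EX_N3_1",
      "metabolites": {
        "N3_1": -1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "EX_N3_2",
      "name": "EX_N3_2",
      "metabolites": {
        "N3_2": -1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "EX_H1",
      "name": "EX_H1",
      "metabolites": {
        "H1": -1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "CONV_N1_1",
      "name": "CONV_N1_1",
      "metabolites": {
        "N1_1": -1,
        "P1": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "CONV_N1_2",
      "name": "CONV_N1_2",
      "metabolites": {
        "N1_2": -1,
        "P1": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "CONV_N2_1",
      "name": "CONV_N2_1",
      "metabolites": {
        "N2_1": -1,
        "P2": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "g1",
      "objective_coefficient": 0
    },
    {
      "id": "CONV_N2_2",
      "name": "CONV_N2_2",
      "metabolites": {
        "N2_2": -1,
        "P2": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "g2 or g3",
      "objective_coefficient": 0
    },
    {
      "id": "CONV_N3_1",
      "name": "CONV_N3_1",
      "metabolites": {
        "N3_1": -1,
        "P3": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "g4 and g5",
      "objective_coefficient": 0
    },
    {
      "id": "CONV_N3_2",
      "name": "CONV_N3_2",
      "metabolites": {
        "N3_2": -1,
        "P3": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "CONV_H1",
      "name": "CONV_H1",
      "metabolites": {
        "H1": -1,
        "P2": 1,
        "P3": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "g6 or g7",
      "objective_coefficient": 0
    },
    {
      "id": "BIOMASS",
      "name": "BIOMASS",
      "metabolites": {
        "P1": -1,
        "P2": -1,
        "P3": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 1
    }
  ],
  "genes": [
    {
      "id": "g1"
    },
    {
      "id": "g2"
    },
    {
      "id": "g3"
    },
    {
      "id": "g4"
    },
    {
      "id": "g5"
    },
    {
      "id": "g6"
    },
    {
      "id": "g7"
    }
  ]
}
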