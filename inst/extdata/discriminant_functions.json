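{
  "resource": "sternal discriminant functions",
  "version": "1.0",
  "orientation": "score above the sectioning point classifies as male",
  "functions": [
    {
      "name": "MW_B_CSW1",
      "variables": ["MW", "B", "CSW1"],
      "coefficients": [0.965, 0.712, 1.793],
      "constant": -17.123,
      "sectioning_point": -0.183,
      "rate_male": 89.0,
      "rate_female": 92.7,
      "rate_overall": 90.6
    },
    {
      "name": "M",
      "variables": ["M"],
      "coefficients": [2.224],
      "constant": -11.653,
      "sectioning_point": 0.07,
      "rate_male": 64.4,
      "rate_female": 72.7,
      "rate_overall": 68.0
    },
    {
      "name": "MW",
      "variables": ["MW"],
      "coefficients": [2.401],
      "constant": -13.642,
      "sectioning_point": -0.1195,
      "rate_male": 78.1,
      "rate_female": 80.0,
      "rate_overall": 78.9
    },
    {
      "name": "B",
      "variables": ["B"],
      "coefficients": [1.008],
      "constant": -9.676,
      "sectioning_point": -0.1185,
      "rate_male": 83.6,
      "rate_female": 81.8,
      "rate_overall": 82.8
    },
    {
      "name": "CSW1",
      "variables": ["CSW1"],
      "coefficients": [3.209],
      "constant": -8.590,
      "sectioning_point": -0.0915,
      "rate_male": 72.6,
      "rate_female": 74.5,
      "rate_overall": 73.4
    },
    {
      "name": "CSW2",
      "variables": ["CSW2"],
      "coefficients": [1.920],
      "constant": -6.117,
      "sectioning_point": -0.072,
      "rate_male": 65.8,
      "rate_female": 69.1,
      "rate_overall": 67.2
    },
    {
      "name": "CL",
      "variables": ["CL"],
      "coefficients": [0.934],
      "constant": -13.991,
      "sectioning_point": -0.1405,
      "rate_male": 84.9,
      "rate_female": 83.6,
      "rate_overall": 84.4
    },
    {
      "name": "SI",
      "variables": ["SI"],
      "coefficients": [0.125],
      "constant": -6.912,
      "sectioning_point": 0.046,
      "rate_male": 69.9,
      "rate_female": 54.5,
      "rate_overall": 63.3
    },
    {
      "name": "SA",
      "variables": ["SA"],
      "coefficients": [0.069],
      "constant": -4.019,
      "sectioning_point": -0.088,
      "rate_male": 84.9,
      "rate_female": 94.5,
      "rate_overall": 89.1
    }
  ]
}
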