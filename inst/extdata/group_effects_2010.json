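{
  "reference": "FT-no-condition",
  "percent_difference": {
    "income": {
      "PT-no-condition": -56.3,
      "FT-diabetes": -6.5,
      "PT-diabetes": -52.4,
      "NILF-diabetes": -88.3
    },
    "welfare": {
      "PT-no-condition": 71.9,
      "FT-diabetes": 24.9,
      "PT-diabetes": 112.3,
      "NILF-diabetes": 3819.8
    },
    "tax": {
      "PT-no-condition": -96.1,
      "FT-diabetes": -24.6,
      "PT-diabetes": -92.6,
      "NILF-diabetes": -99.8
    }
  },
  "ci95": {
    "income": {
      "PT-no-condition": [-58.7, -53.7],
      "FT-diabetes": [-13.2, 0.7],
      "PT-diabetes": [-60.2, -43.1],
      "NILF-diabetes": [-95.6, -69.3]
    }
  }
}
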