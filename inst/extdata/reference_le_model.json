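{
  "no_cspca": {
    "shape": 1.56678289469588,
    "coefficients": {
      "intercept": 3.43665926231777,
      "age": -0.0369006031642746,
      "charlson1": -0.177588428049155,
      "charlson2plus": -0.451169649726284
    },
    "relative_mortality": 1.60235108356674,
    "n": 19247,
    "n_deaths": 7347
  },
  "cspca": {
    "shape": 1.4,
    "strata": [
      {
        "age_band": "55-59",
        "charlson": "0",
        "scale": 16.018900729266,
        "le_years": 14.6
      },
      {
        "age_band": "55-59",
        "charlson": "1",
        "scale": 14.0439677626442,
        "le_years": 12.8
      },
      {
        "age_band": "55-59",
        "charlson": "2+",
        "scale": 11.520442305294,
        "le_years": 10.5
      },
      {
        "age_band": "60-64",
        "charlson": "0",
        "scale": 14.8119972496638,
        "le_years": 13.5
      },
      {
        "age_band": "60-64",
        "charlson": "1",
        "scale": 13.0565012793332,
        "le_years": 11.9
      },
      {
        "age_band": "60-64",
        "charlson": "2+",
        "scale": 10.6426943201288,
        "le_years": 9.7
      },
      {
        "age_band": "65-69",
        "charlson": "0",
        "scale": 13.4953752719159,
        "le_years": 12.3
      },
      {
        "age_band": "65-69",
        "charlson": "1",
        "scale": 11.849597799731,
        "le_years": 10.8
      },
      {
        "age_band": "65-69",
        "charlson": "2+",
        "scale": 9.76494633496352,
        "le_years": 8.9
      },
      {
        "age_band": "70-74",
        "charlson": "0",
        "scale": 11.9593162978767,
        "le_years": 10.9
      },
      {
        "age_band": "70-74",
        "charlson": "1",
        "scale": 10.5329758219831,
        "le_years": 9.6
      },
      {
        "age_band": "70-74",
        "charlson": "2+",
        "scale": 8.55804285536128,
        "le_years": 7.8
      },
      {
        "age_band": "75+",
        "charlson": "0",
        "scale": 10.6426943201288,
        "le_years": 9.7
      },
      {
        "age_band": "75+",
        "charlson": "1",
        "scale": 9.32607234238089,
        "le_years": 8.5
      },
      {
        "age_band": "75+",
        "charlson": "2+",
        "scale": 7.68029487019602,
        "le_years": 7
      }
    ]
  },
  "fit_metadata": {
    "seed": 1,
    "source": "synthetic reference cohorts (generator defaults)",
    "date": "2026-09-20"
  }
}
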