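{
  "predictor_set": ["age", "psa", "free_psa_pct"],
  "coefficients": {
    "age": 0.0669227612306186,
    "psa": 0.998203907334371,
    "free_psa_pct": -1.78762569194063
  },
  "intercept": -7.58720252607573,
  "centering": {
    "psa": 2.14847134407019,
    "free_psa_pct": -2.32827166995878
  },
  "fit_metadata": {
    "n": 3616,
    "n_cspca": 342,
    "date": "2026-09-20",
    "seed": 1,
    "source": "synthetic reference cohort (cohort_config defaults)"
  }
}
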