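{
  "path": "hepatitis.data",
  "format": "csv",
  "header": false,
  "class_col": 1,
  "missing_marker": "?",
  "kinds": ["continuous", "categorical", "categorical", "categorical",
            "categorical", "categorical", "categorical", "categorical",
            "categorical", "categorical", "categorical", "categorical",
            "categorical", "continuous", "continuous", "continuous",
            "continuous", "continuous", "categorical"],
  "stages": ["impute", "normalize"],
  "per_fold": false
}
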