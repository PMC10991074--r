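{
  "country": "US",
  "scale": "MIST-20",
  "n": 3479,
  "notes": "MIST-20 general population norms for the United States: percentile-to-score grids for veracity discernment (V), fake news detection (f) and real news detection (r), on a 0-100 grid in steps of 5.",
  "grids": {
    "V": {
      "percentile": [0, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90, 95, 100],
      "score":      [4, 8,  9, 10, 10, 11, 12, 12, 13, 14, 14, 15, 15, 16, 16, 17, 17, 18, 19, 19, 20]
    },
    "f": {
      "percentile": [0, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90, 95, 100],
      "score":      [0, 3,  4,  5,  5,  6,  7,  7,  7,  8,  8,  8,  9,  9,  9,  9, 10, 10, 10, 10, 10]
    },
    "r": {
      "percentile": [0, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90, 95, 100],
      "score":      [0, 2,  3,  4,  4,  5,  5,  6,  6,  7,  7,  7,  7,  8,  8,  8,  9,  9, 10, 10, 10]
    }
  },
  "quartiles": {
    "V": {"min": 4, "q1": 11, "median": 14, "mean": 14, "q3": 17, "max": 20}
  }
}
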