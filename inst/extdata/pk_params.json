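{
  "levetiracetam": {"ka": 3.7, "ke": 0.099, "scale": 0.01,
    "comment": "half-life ~7 h, tmax ~1 h"},
  "lamotrigine": {"ka": 2.3, "ke": 0.024, "scale": 0.01,
    "comment": "half-life ~29 h, tmax ~2 h"},
  "carbamazepine": {"ka": 0.41, "ke": 0.046, "scale": 0.01,
    "comment": "half-life ~15 h, tmax ~6 h (controlled release)"},
  "valproate": {"ka": 1.1, "ke": 0.05, "scale": 0.01,
    "comment": "half-life ~14 h, tmax ~3 h"}
}
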