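{
  "name": "suicidality",
  "allow_overlap": false,
  "subtypes": {
    "ideation": ["R45.851"],
    "self_harm": ["R45.88", "Z91.5", "Z91.51", "Z91.52"],
    "attempt": ["T14.91", "T14.91XA", "T14.91XD", "T14.91XS"]
  }
}
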