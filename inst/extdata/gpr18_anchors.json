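{
  "chain": "A",
  "segments": [
    {"segment": 1,  "start": 26,  "end": 53,  "anchor": 40},
    {"segment": 2,  "start": 61,  "end": 85,  "anchor": 68},
    {"segment": 23, "start": 86,  "end": 89,  "anchor": 87},
    {"segment": 3,  "start": 95,  "end": 127, "anchor": 119},
    {"segment": 4,  "start": 140, "end": 163, "anchor": 146},
    {"segment": 45, "start": 170, "end": 174, "anchor": 172},
    {"segment": 5,  "start": 179, "end": 211, "anchor": 199},
    {"segment": 6,  "start": 220, "end": 256, "anchor": 247},
    {"segment": 7,  "start": 259, "end": 290, "anchor": 283}
  ]
}
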