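[
  {
    "name": "BsmAI",
    "recognition": "GTCTC",
    "cut_top": 6,
    "cut_bottom": 10,
    "note": "type IIS, GTCTC(1/5): top cut 1 nt and bottom cut 5 nt downstream of the recognition site"
  },
  {
    "name": "RsaI",
    "recognition": "GTAC",
    "cut_top": 2,
    "cut_bottom": 2,
    "note": "palindromic blunt cutter, GT^AC"
  },
  {
    "name": "BseYI",
    "recognition": "CCCAGC",
    "cut_top": 1,
    "cut_bottom": 5,
    "note": "non-palindromic, C^CCAGC with the bottom-strand cut after the 5th recognition base"
  }
]
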