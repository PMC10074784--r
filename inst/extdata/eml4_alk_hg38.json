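{
  "name": "EML4-ALK",
  "build": "hg38",
  "five_prime": {
    "chrom": "chr2",
    "start": 42169353,
    "end": 42332548,
    "strand": "+",
    "label": "EML4"
  },
  "three_prime": {
    "chrom": "chr2",
    "start": 29192774,
    "end": 29921586,
    "strand": "-",
    "label": "ALK"
  },
  "min_pairs": 2,
  "min_clip_reads": 2,
  "flank_len": 20
}
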