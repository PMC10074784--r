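{
  "name": "EML4-ALK",
  "build": "hg19",
  "note": "DERIVED coordinates: the hg38 windows equal the EML4/ALK RefSeq gene spans on hg38; these are the corresponding RefSeq gene spans on hg19. Override via loadTargetConfig() if your pipeline uses different hg19 windows.",
  "five_prime": {
    "chrom": "chr2",
    "start": 42396490,
    "end": 42559688,
    "strand": "+",
    "label": "EML4"
  },
  "three_prime": {
    "chrom": "chr2",
    "start": 29415640,
    "end": 30144432,
    "strand": "-",
    "label": "ALK"
  },
  "min_pairs": 2,
  "min_clip_reads": 2,
  "flank_len": 20
}
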