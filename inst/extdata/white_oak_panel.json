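{
  "name": "white_oak_cp_panel",
  "loci": [
    {
      "name": "psaI-ycf4",
      "forward_primer": { "name": "psaI", "seq": "CGTGTGTAAACATGATATATGAG", "dye": "FAM" },
      "reverse_primer": { "name": "ycf4", "seq": "GAGTAATTCATCGAATTGGTTAG", "dye": "none" },
      "expected_lengths": { "Asia": 174, "Europe": 178, "NorthAmerica": 178 }
    },
    {
      "name": "psbE-petL",
      "forward_primer": { "name": "psbE", "seq": "AAGGAATTGGTTAGTTGTCCAG", "dye": "VIC" },
      "reverse_primer": { "name": "petL", "seq": "TTACATATCTTAAATTAGAGAGCC", "dye": "none" },
      "expected_lengths": { "Asia": 179, "Europe": 185, "NorthAmerica": 185 }
    },
    {
      "name": "trnLF",
      "forward_primer": { "name": "trnL1", "seq": "CAATACATATCATTTCTTGTACTG", "dye": "PET" },
      "reverse_primer": { "name": "trnF2", "seq": "TAGATAACTTGAGTTTATGTCAATT", "dye": "none" },
      "expected_lengths": { "Asia": 135, "Europe": 135, "NorthAmerica": 130 }
    },
    {
      "name": "trnCD",
      "forward_primer": { "name": "trnC5", "seq": "TTGGATAGACGAACGGGGAAT", "dye": "FAM" },
      "reverse_primer": { "name": "trnD5", "seq": "TATCATATTAAATTGATTGCCGG", "dye": "none" },
      "expected_lengths": { "Asia": 123, "Europe": 123, "NorthAmerica": 115 }
    },
    {
      "name": "trnDT",
      "forward_primer": { "name": "trnD3", "seq": "GGATAGGGATCAACAAGTTATTG", "dye": "PET" },
      "reverse_primer": { "name": "trnT4", "seq": "CAAGACCGACCCTAATTGAAT", "dye": "PET" },
      "expected_lengths": { "Asia": 187, "Europe": 187, "NorthAmerica": 189 },
      "digest": {
        "enzyme": "HinfI",
        "site": "GANTC",
        "cut_offset": 1,
        "expected_labeled": {
          "Asia": [86, 71],
          "Europe": [86, 101],
          "NorthAmerica": [88, 101]
        }
      }
    }
  ]
}
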