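{
  "_comments": [
    "Five-reaction multiplex PCR-SSP panel for KIR3DL1/KIR3DS1 functional subtyping.",
    "Primer sequences and amplicon sizes transcribed bit-exact from the published primer table;",
    "annealing/extension/cycle/concentration metadata from the reaction-conditions table is inert",
    "(carried for provenance, never used in computation).",
    "DISCREPANCY: the running text twice states a 650 bp internal control band, but the primer",
    "table prints 607 bp for the HLA-DR control pair; 607 is recorded here. The true wet-lab",
    "product size is not resolvable from the publication.",
    "Reaction 4 produces two sizes: the activating-gene (KIR3DS1) intron 3 is 360 bp longer",
    "than the inhibitory-gene intron 3, so its product runs 1933 bp vs 1573 bp."
  ],
  "control": {
    "forward": { "name": "FDRA-360", "seq": "GAGGTAACTGTGCTCACGAACAGC" },
    "reverse": { "name": "RDRA-633", "seq": "CACGTTCTCTGTAGTCTCTGGG" },
    "expected_size": 607
  },
  "reactions": [
    {
      "id": "R1",
      "targets": ["NULL"],
      "forward": { "name": "ConsF", "seq": "ATCCTGTGCGCTGCTGAGCTGAG" },
      "reverse": { "name": "193G-R", "seq": "CATGGAAGATGGGAATGTGGATTCC" },
      "expected_sizes": { "KIR3DL1": 2019 },
      "metadata": { "annealing_c": 66.9, "extension_min": "3:30", "cycles": 30,
                    "primer_um": 0.795, "control_um": 0.040 }
    },
    {
      "id": "R2",
      "targets": ["LOW1"],
      "forward": { "name": "202A2-F", "seq": "CAATTTCATGCTATACAAAGAAGACA" },
      "reverse": { "name": "607T-R", "seq": "GGGRGCTGACAACTGATAGGA" },
      "expected_sizes": { "KIR3DL1": 1573 },
      "metadata": { "annealing_c": 65.6, "extension_min": "3:30", "cycles": 30,
                    "primer_um": 0.795, "control_um": 0.040 }
    },
    {
      "id": "R3",
      "targets": ["HIGH1"],
      "forward": { "name": "202A3-F", "seq": "GCTATACAAAGAAGACAGAATCCACA" },
      "reverse": { "name": "607C-R", "seq": "GGGAGCTGACAACTGATAGGG" },
      "expected_sizes": { "KIR3DL1": 1573 },
      "metadata": { "annealing_c": 67.0, "extension_min": "3:45", "cycles": 35,
                    "primer_um": 0.795, "control_um": 0.173 }
    },
    {
      "id": "R4",
      "targets": ["HIGH2", "S1"],
      "forward": { "name": "202G-F", "seq": "CAAAGAAGACAGAATCCACG" },
      "reverse": { "name": "607C-R", "seq": "GGGAGCTGACAACTGATAGGG" },
      "expected_sizes": { "KIR3DL1": 1573, "KIR3DS1": 1933 },
      "metadata": { "annealing_c": 64.2, "extension_min": "4:00", "cycles": 35,
                    "primer_um": 0.795, "control_um": 0.040 }
    },
    {
      "id": "R5",
      "targets": ["LOW2"],
      "forward": { "name": "int6-F", "seq": "CAGAGATCTGTGCCAGC" },
      "reverse": { "name": "1021/22-S-R", "seq": "GAGGTCCCAATCAGAACG" },
      "expected_sizes": { "KIR3DL1": 1408 },
      "metadata": { "annealing_c": 64.2, "extension_min": "3:45", "cycles": 35,
                    "primer_um": 0.795, "control_um": 0.086 }
    }
  ]
}
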