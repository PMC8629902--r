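# CTCF zinc-finger architecture, config version 1.
#
# Per-finger coordinating anchors (c1, c2 = cysteines; h1, h2 = histidines,
# h2 is a cysteine in the C-terminal C2HC finger). The DNA-binding helix is
# numbered -6..+6 over the 12 residues ending immediately before h1, which
# places the canonical anchors L309 at ZF2 +4, R339 at ZF3 +6, K365 at
# ZF4 +3 and G420 at ZF6 +2, with R377 in the ZF4/ZF5 linker and H284 a
# ZF1 coordinating histidine.
name: CTCF
length: 727
domains:
  name: ["N", "Z", "C"]
  start: [1, 266, 579]
  end: [265, 578, 727]
zfs:
  - {index: 1,  c1: 268, c2: 271, h1: 284, h2: 289, type: C2H2}
  - {index: 2,  c1: 296, c2: 299, h1: 312, h2: 317, type: C2H2}
  - {index: 3,  c1: 324, c2: 327, h1: 340, h2: 345, type: C2H2}
  - {index: 4,  c1: 353, c2: 356, h1: 369, h2: 374, type: C2H2}
  - {index: 5,  c1: 381, c2: 384, h1: 397, h2: 402, type: C2H2}
  - {index: 6,  c1: 409, c2: 412, h1: 425, h2: 430, type: C2H2}
  - {index: 7,  c1: 437, c2: 440, h1: 453, h2: 458, type: C2H2}
  - {index: 8,  c1: 470, c2: 473, h1: 486, h2: 491, type: C2H2}
  - {index: 9,  c1: 498, c2: 501, h1: 514, h2: 519, type: C2H2}
  - {index: 10, c1: 526, c2: 529, h1: 542, h2: 547, type: C2H2}
  - {index: 11, c1: 557, c2: 560, h1: 573, h2: 578, type: C2HC}
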