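schiff_base_pos: 296
schiff_base_expected: K
counterion_vertebrate_pos: 113
counterion_ancestral_pos: 181
counterion_ancestral_expected: E
dry_span:
- 134
- 136
dry_134:
- D
- E
dry_136:
- 'Y'
- F
- W
- C
- S
- H
npxxy_span:
- 302
- 313
triad_span:
- 310
- 312
disulfide_pair:
- 110
- 187
palmitoylation_pair:
- 322
- 323
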