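id	name	family	is_anchor
Rn-rhodopsin-synthetic	Rn-rhodopsin	ciliary	TRUE
Sp-opsin_1	Sp-opsin 1	ciliary	FALSE
Sp-opsin_2	Sp-opsin 2	basal-branch	FALSE
Sp-opsin_3.1	Sp-opsin 3.1	Go	FALSE
Sp-opsin_3.2	Sp-opsin 3.2	Go	FALSE
Sp-opsin_4	Sp-opsin 4	rhabdomeric	FALSE
Sp-opsin_5	Sp-opsin 5	basal-branch	FALSE
Sp-opsin_6	Sp-opsin 6	peropsin	FALSE
Sp-opsin_7	Sp-opsin 7	RGR	FALSE
Sp-opsin_8	Sp-opsin 8	neuropsin	FALSE
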