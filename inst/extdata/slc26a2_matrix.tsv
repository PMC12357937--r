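taxon	A1p	R1	Q1	O2	N1	N2
tetrapod_outgroup	1	0	0	0	0	0
basal_rayfinned	1	1	0	0	0	0
elopomorpha_ostariophysi	1	1	0	0	0	0
salmoniformes_esociformes_argentiniformes	1	1	0	0	0	0
osmeriformes_stomiiformes	1	1	0	1	0	0
galaxiiformes	1	1	1	0	0	0
eurypterygii_other	1	1	1	0	0	0
straightnose_pipefish	1	1	1	0	0	0
seahorse_clade	0	1	1	0	0	0
basal_notothenioids	1	1	1	0	0	0
notothenioid_crown	1	1	1	0	1	1
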