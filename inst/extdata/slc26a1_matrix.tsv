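taxon	A1	E1	E2	E3	E4	E5	O1
tetrapod_outgroup	1	0	0	0	0	0	0
basal_rayfinned	1	0	0	0	0	0	0
elopomorpha_ostariophysi	1	0	0	0	0	0	0
salmoniformes_esociformes_argentiniformes	1	0	0	0	0	0	0
osmeriformes_stomiiformes	1	0	0	0	0	0	1
galaxiiformes	1	1	0	0	1	0	0
eurypterygii_other	1	1	1	1	1	1	0
straightnose_pipefish	1	1	1	1	1	1	0
seahorse_clade	1	1	1	1	1	1	0
basal_notothenioids	1	1	1	1	1	1	0
notothenioid_crown	1	1	1	1	1	1	0
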