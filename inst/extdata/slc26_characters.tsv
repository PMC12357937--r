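family	character	column	phase	note
slc26a1	E1	55	0	Eurypterygii/Galaxiiformes gain (intron 1); SYNTHETIC schematic column
slc26a1	A1	132	0	ancient jawed-vertebrate intron; SYNTHETIC schematic column
slc26a1	E2	240	1	Eurypterygii gain (intron 3); SYNTHETIC schematic column
slc26a1	O1	248	0	Osmeriformes/Stomiiformes gain, 23 nt from E2; SYNTHETIC schematic column
slc26a1	E3	375	2	Eurypterygii gain (intron 4); SYNTHETIC schematic column
slc26a1	E4	480	0	Eurypterygii/Galaxiiformes gain (intron 5); SYNTHETIC schematic column
slc26a1	E5	600	1	Eurypterygii gain (intron 6); SYNTHETIC schematic column
slc26a2	A1p	132	0	ancient jawed-vertebrate intron; SYNTHETIC schematic column
slc26a2	Q1	150	1	Eurypterygii/Galaxiiformes gain (intron 2); SYNTHETIC schematic column
slc26a2	O2	152	2	Osmeriformes/Stomiiformes gain, 7 nt from Q1; SYNTHETIC schematic column
slc26a2	N1	220	0	notothenioid gain (intron 3); SYNTHETIC schematic column
slc26a2	R1	310	0	ray-finned gain (intron 2 of three-exon genes); SYNTHETIC schematic column
slc26a2	N2	400	2	notothenioid gain (intron 5); SYNTHETIC schematic column
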