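# Per-residue structural environment for the bundled talin-1 catalog positions.
# location_class and bh are annotation-supplied (explicit-table mode); rsa unused here.
position	location_class	bh	rsa
229	buried	1	NA
392	buried	0	NA
577	buried	0	NA
893	buried	1	NA
1368	surface	0	NA
1389	buried	0	NA
1539	buried	0	NA
1750	buried	0	NA
1770	surface	0	NA
2086	surface	0	NA
2509	surface	0	NA
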