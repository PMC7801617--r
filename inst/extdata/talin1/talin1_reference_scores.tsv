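# Printed reference triage outputs for the bundled talin-1 catalog:
# domain assignment, location label and final composite score per mutation.
# Used as calibration targets for weight fitting and as the regression
# reference for the bundled case.
id	domain	location	final_score
P229L	F2	BH/buried	8.20
I392N	F3	Buried	8.95
V577D	R1	Buried	8.39
A893E	R3	BH/buried	7.63
R1368W	R7	Surface	7.75
Y1389C	R7	Buried	8.58
L1539P	R8	Buried	8.45
S1750F	R9	Buried	7.55
E1770Q	R9	Surface	6.01
D2086V	R11	Surface	7.71
L2509P	DD	Surface	7.46
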