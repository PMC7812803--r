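compartment	subpop	percent	sem	printed
div4	EARLY	34.5	2.69	TRUE
div5	EARLY	17.9	1.71	TRUE
div6	EARLY	9.30	1.45	TRUE
div4	LATE_INT	29.2	3.03	TRUE
div5	LATE_INT	39.0	2.26	TRUE
div6	LATE_INT	37.2	0.994	TRUE
div4	LATE_LO	6.29	1.02	TRUE
div5	LATE_LO	11.0	1.33	TRUE
div6	LATE_LO	19.4	2.09	TRUE
div4	DZ_CMYC	7.51	1.33	TRUE
div5	DZ_CMYC	11.9	1.28	TRUE
div6	DZ_CMYC	14.8	1.31	TRUE
div4	PREPB	NA	NA	FALSE
div5	PREPB	NA	NA	FALSE
div6	PREPB	NA	NA	FALSE
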