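# Default compound library, v1 — SYNTHETIC reconstruction of a 26-bile-acid
# panel (unconjugated cores, glycine/taurine conjugates, sulfates) plus
# representative lysophospholipids and class-matched internal standards.
# Formulas follow cholanoic-acid conjugation chemistry; retention times are
# plausible reversed-phase values used by the simulator, not measured ones.
# nominal_is_concentration in µM (internal-standard rows only).
name	class_tag	formula	adduct	expected_rt	rt_source	is_internal_standard	internal_standard_ref	nominal_is_concentration
CA	bile-acid	C24H40O5	[M-H]-	7.10	standard	FALSE	CA-d4	NA
CDCA	bile-acid	C24H40O4	[M-H]-	9.40	standard	FALSE	CA-d4	NA
DCA	bile-acid	C24H40O4	[M-H]-	9.80	standard	FALSE	CA-d4	NA
UDCA	bile-acid	C24H40O4	[M-H]-	6.30	standard	FALSE	CA-d4	NA
HDCA	bile-acid	C24H40O4	[M-H]-	6.70	standard	FALSE	CA-d4	NA
HCA	bile-acid	C24H40O5	[M-H]-	5.90	standard	FALSE	CA-d4	NA
LCA	bile-acid	C24H40O3	[M-H]-	12.40	standard	FALSE	CA-d4	NA
aMCA	bile-acid	C24H40O5	[M-H]-	4.60	standard	FALSE	CA-d4	NA
bMCA	bile-acid	C24H40O5	[M-H]-	4.90	standard	FALSE	CA-d4	NA
wMCA	bile-acid	C24H40O5	[M-H]-	4.30	standard	FALSE	CA-d4	NA
GCA	glycine-conjugate	C26H43NO6	[M-H]-	5.30	standard	FALSE	GCA-d5	NA
GCDCA	glycine-conjugate	C26H43NO5	[M-H]-	7.60	standard	FALSE	GCA-d5	NA
GDCA	glycine-conjugate	C26H43NO5	[M-H]-	8.10	standard	FALSE	GCA-d5	NA
GUDCA	glycine-conjugate	C26H43NO5	[M-H]-	4.70	standard	FALSE	GCA-d5	NA
GHDCA	glycine-conjugate	C26H43NO5	[M-H]-	5.10	standard	FALSE	GCA-d5	NA
GHCA	glycine-conjugate	C26H43NO6	[M-H]-	4.40	standard	FALSE	GCA-d5	NA
GLCA	glycine-conjugate	C26H43NO4	[M-H]-	10.90	standard	FALSE	GCA-d5	NA
TCA	taurine-conjugate	C26H45NO7S	[M-H]-	4.95	standard	FALSE	TCA-d5	NA
TCDCA	taurine-conjugate	C26H45NO6S	[M-H]-	7.20	standard	FALSE	TCA-d5	NA
TDCA	taurine-conjugate	C26H45NO6S	[M-H]-	7.75	standard	FALSE	TCA-d5	NA
TUDCA	taurine-conjugate	C26H45NO6S	[M-H]-	4.10	standard	FALSE	TCA-d5	NA
THDCA	taurine-conjugate	C26H45NO6S	[M-H]-	4.55	standard	FALSE	TCA-d5	NA
TLCA	taurine-conjugate	C26H45NO5S	[M-H]-	10.30	standard	FALSE	TCA-d5	NA
LCA-S	sulfate	C24H40O6S	[M-H]-	8.70	standard	FALSE	CA-d4	NA
GLCA-S	glycine-conjugate+sulfate	C26H43NO7S	[M-H]-	6.90	standard	FALSE	GCA-d5	NA
TLCA-S	taurine-conjugate+sulfate	C26H45NO8S	[M-H]-	6.10	standard	FALSE	TCA-d5	NA
CA-d4	bile-acid	C24H36D4O5	[M-H]-	7.08	standard	TRUE		25
GCA-d5	glycine-conjugate	C26H38D5NO6	[M-H]-	5.28	standard	TRUE		25
TCA-d5	taurine-conjugate	C26H40D5NO7S	[M-H]-	4.93	standard	TRUE		25
LPC(16:0)	LPC+fatty-acyl(16:0)	C24H50NO7P	[M+CH3COO]-	10.40	standard	FALSE	LPC(17:0)	NA
LPC(18:2)	LPC+fatty-acyl(18:2)	C26H50NO7P	[M+CH3COO]-	9.90	standard	FALSE	LPC(17:0)	NA
O-LPC(16:0)	O-LPC+fatty-acyl(16:0)	C24H52NO6P	[M+CH3COO]-	11.20	predicted	FALSE	LPC(17:0)	NA
LPE(18:2)	LPE+fatty-acyl(18:2)	C23H44NO7P	[M-H]-	9.70	standard	FALSE	LPC(17:0)	NA
LPI(18:0)	LPI+fatty-acyl(18:0)	C27H53O12P	[M-H]-	10.10	standard	FALSE	LPC(17:0)	NA
LPG(16:0)	LPG+fatty-acyl(16:0)	C22H45O9P	[M-H]-	9.60	predicted	FALSE	LPC(17:0)	NA
LPS(18:1)	LPS+fatty-acyl(18:1)	C24H46NO9P	[M-H]-	9.30	predicted	FALSE	LPC(17:0)	NA
LPC(17:0)	LPC+fatty-acyl(17:0)	C25H52NO7P	[M+CH3COO]-	10.70	standard	TRUE		25
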