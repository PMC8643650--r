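@HD	VN:1.6	SO:coordinate
@SQ	SN:chr1	LN:100000
@SQ	SN:chr2	LN:80000
r1	0	chr1	101	60	20M	*	0	0	ACGTACGTACGTACGTACGT	*
r2	0	chr1	501	5	20M	*	0	0	ACGTACGTACGTACGTACGT	*
r3	256	chr1	901	60	20M	*	0	0	*	*
r4	2048	chr2	51	60	20M	*	0	0	ACGTACGTACGTACGTACGT	*
r5	0	chr2	1001	30	20M	*	0	0	ACGTACGTACGTACGTACGT	*
r6	4	*	0	0	*	*	0	0	ACGTACGTACGTACGTACGT	*
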