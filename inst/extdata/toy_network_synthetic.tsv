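#	R1	R2	R3	R4	R5	R6	R7r	R8	R9	R10	R11
#rev	0	0	0	0	0	0	1	0	0	0	0
X1	-2	-1	-2	2	1	1	0	0	0	0	0
X2	-1	-3/2	-2	2	1	0	-1	0	0	0	0
X3	1	1/2	1	-2	0	0	0	1	0	0	0
X4	-1	-1/2	-1	1	0	0	0	0	1	0	0
X5	-2	-1	-2	2	1	0	0	0	0	1	0
X6	0	0	0	0	-1	0	0	0	0	0	1
X7	-3	-5/2	-4	4	2	1	-1	0	0	0	0
X8	0	-1	-1	0	1	0	-1	1	0	0	0
X9	0	0	0	-1	0	0	0	1	1	0	0
X10	-3	-3/2	-3	3	1	0	0	0	1	1	0
X11	-2	-1	-2	2	0	0	0	0	0	1	1
X12	-2	-1	-2	2	0	1	0	0	0	0	1
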