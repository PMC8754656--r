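protein	sample1	sample2	control1	control2	element
SYNBG1	5	4	3	2	S1606
SYNBG2	7	0	0	0	S1606
SYNBG3	0	0	0	0	S1606
SYNBG4	3	2	1	0	S961
SYNBG5	0	6	0	0	S961
SYNBG6	2	2	0	4	S961
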