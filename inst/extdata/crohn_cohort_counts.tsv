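cn	case_count	control_count
0	14	4
1	119	49
2	331	149
3	124	45
4	21	5
5	4	0
6	1	0
7	1	0
8	0	0
9	1	0
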