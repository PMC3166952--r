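cn	case_count	control_count
0	2	4
1	51	49
2	139	149
3	49	45
4	10	5
5	1	0
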