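cn	case_count	control_count
0	6	4
1	25	56
2	115	143
3	45	49
4	2	11
5	2	2
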