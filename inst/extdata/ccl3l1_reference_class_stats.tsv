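integer_cn	n_samples	mean	sd	normalised_sd	probability_of_error
0	30	-0.033	0.068	NA	NA
1	300	1.033	0.097	0.096	7.2e-07
2	877	2.021	0.142	0.071	4.9e-04
3	313	3.012	0.178	0.059	4.9e-03
4	49	4.071	0.203	0.051	1.9e-02
5	9	4.977	0.346	0.069	0.149
6	1	NA	NA	NA	NA
7	1	NA	NA	NA	NA
8	0	NA	NA	NA	NA
9	1	NA	NA	NA	NA
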