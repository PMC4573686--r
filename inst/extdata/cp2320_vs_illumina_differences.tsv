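pos_a	kind	len	region
1355	insertion_in_A	61	LSC
1426	substitution	1	LSC
1430	insertion_in_A	1	LSC
12633	insertion_in_A	1	LSC
29255	deletion_in_A	5	LSC
35514	deletion_in_A	2	LSC
45756	substitution	1	LSC
45773	deletion_in_A	1	LSC
45776	deletion_in_A	1	LSC
45780	deletion_in_A	1	LSC
51980	deletion_in_A	4	LSC
56686	deletion_in_A	1	LSC
60118	insertion_in_A	2	LSC
63266	substitution	1	LSC
84321	insertion_in_A	1	IR1
96607	deletion_in_A	6	IR1
100122	deletion_in_A	1	IR1
111817	substitution	6	SSC
111858	insertion_in_A	45	SSC
114513	substitution	1	SSC
117806	deletion_in_A	1	SSC
136237	deletion_in_A	6	IR2
148514	insertion_in_A	1	IR2
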