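sample_id	group	z	pair
S1	0	2.287	1
S2	1	-1.197	1
S3	0	-0.694	2
S4	1	-0.412	2
S5	0	-0.971	3
S6	1	-0.947	3
S7	0	0.748	4
S8	1	-0.117	4
S9	0	0.153	5
S10	1	2.19	5
S11	0	0.357	6
S12	1	2.717	6
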