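sample_id	OTU1	OTU2	OTU3	OTU4	OTU5	OTU6	OTU7	OTU8	OTU9	OTU10	OTU11	OTU12	OTU13	OTU14	OTU15	OTU16	OTU17	OTU18	OTU19	OTU20	OTU21	OTU22	OTU23	OTU24	OTU25	OTU26	OTU27	OTU28	OTU29	OTU30	OTU31	OTU32	OTU33	OTU34	OTU35	OTU36	OTU37	OTU38	OTU39	OTU40
S1	9	13	10	46	9	5	3	13	24	14	10	15	75	3	13	46	1	1	3	0	7	4	7	2	17	0	0	14	43	6	6	21	36	4	13	4	0	2	1	0
S2	0	54	0	26	6	7	1	7	10	7	37	7	51	4	13	56	17	1	3	8	25	3	8	9	0	13	0	5	36	2	12	26	14	8	6	11	0	4	3	0
S3	2	26	14	15	17	6	23	15	19	9	12	14	77	10	12	37	7	0	1	5	18	3	17	1	24	11	0	2	40	0	10	30	9	3	2	1	0	1	1	6
S4	2	25	0	63	4	20	14	5	5	2	27	2	86	6	4	16	28	2	12	5	32	5	0	5	6	18	2	11	21	0	4	21	13	3	11	3	0	17	0	0
S5	0	11	2	30	10	1	13	9	14	18	8	7	66	15	3	23	26	1	1	6	4	15	0	18	10	6	0	13	58	21	18	49	1	5	4	8	0	6	0	0
S6	3	27	6	20	2	3	4	9	8	19	27	14	50	7	8	51	2	6	5	7	6	27	2	6	7	7	2	5	22	0	38	24	13	21	24	5	0	3	0	10
S7	6	32	0	8	15	2	1	33	26	8	35	5	41	2	21	48	2	0	0	1	23	13	4	4	7	15	0	5	40	1	28	36	1	2	11	6	0	16	2	0
S8	0	35	8	4	15	1	3	9	27	2	8	30	84	11	6	39	3	0	0	1	0	7	0	6	13	2	0	23	41	2	37	31	11	5	6	16	0	9	5	0
S9	2	29	18	33	5	15	7	2	9	20	24	3	53	11	3	65	6	4	1	6	23	5	0	15	0	5	0	38	28	0	31	17	2	2	10	8	0	0	0	0
S10	0	19	3	24	3	2	0	1	20	4	14	5	123	8	7	30	18	3	2	6	3	10	8	3	10	5	8	29	19	0	26	17	36	5	16	9	0	3	1	0
S11	5	18	12	22	4	2	1	8	7	11	22	13	70	11	6	63	4	1	5	2	9	15	11	9	28	9	0	9	39	0	18	29	3	6	5	7	0	11	2	3
S12	4	27	28	19	6	3	2	1	11	21	56	1	65	12	2	44	6	0	0	4	6	0	10	14	16	6	0	19	28	1	23	24	8	5	11	10	0	7	0	0
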