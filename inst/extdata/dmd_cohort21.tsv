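family_id	gestational_age	variant_label	ff_percent	sex	n_type1	n_type2	bf	nipd_result	invasive_result
P1	11+0	EX53_55del	4.92	Male	354	354	2.70e47	Affected	Affected
P2	12+0	EX46_48del	5.91	Female	311	180	1.80e80	Carrier	Carrier
P3	11+0	EX12_13dup	5.50	Female	183	217	5.10e-29	Normal	Normal
P4	12+3	c.3055C > T	6.21	Female	134	220	3.30e-28	Normal	Normal
P5	9+0	EX45_50del	3.96	Male	365	365	1.40e-99	Normal	Normal
P6	9+5	c.3786+2T > A	6.27	Male	528	528	2.70e162	Affected	Affected
P7	8+6	EX10_11dup	8.21	Female	184	205	2.40e-110	Normal	Normal
P8	10+5	EX3_4del	5.71	Female	198	166	5.00e38	Carrier	Carrier
P9	9+1	EX8_26del	11.07	Female	459	459	6.90e-300	Normal	Normal
P10	8+0	EX45_51del	1.87	Female	154	141	1.30e8	Carrier	Carrier
P11	7+3	EX10_13del	5.54	Female	178	179	1.10e29	Carrier	Carrier
P12	11+5	EX48_50del	7.14	Male	333	333	4.40e279	Affected	Affected
P13	8+0	EX8_9dup	11.68	Female	274	274	1.10e180	Carrier	Carrier
P14	9+1	EX50del	5.26	Female	120	108	4.90e9	Carrier	Carrier
P15	11+0	EX45_55del	5.88	Male	406	406	6.30e-142	Normal	Normal
P16	8+0	EX46_51del	7.58	Male	687	687	1.20e168	Affected	Affected
P17	8+1	EX3_25dup	9.24	Male	349	349	1.00e-300	Normal	Normal
P18	11+5	EX48_52del	6.37	Female	447	302	1.80e123	Carrier	Carrier
P19	18+0	EX8_9dup	6.44	Female	131	131	3.20e31	Carrier	Carrier
P20	13+0	EX45_47del	5.58	Female	97	152	4.40e22	Carrier	Carrier
P21	13+4	EX8_9dup	6.32	Male	619	619	5.20e-173	Normal	Normal
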