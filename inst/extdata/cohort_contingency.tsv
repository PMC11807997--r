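variable	level	AD	MCI	CN
gender	male	27	14	22
gender	female	30	29	40
smoking	yes	15	8	10
smoking	no	42	35	52
hypertension	yes	22	15	31
hypertension	no	35	28	31
diabetes	yes	11	5	16
diabetes	no	46	38	46
hyperlipidemia	yes	23	23	35
hyperlipidemia	no	34	20	27
heart_disease	yes	16	10	10
heart_disease	no	41	33	52
cerebrovascular_disease	yes	14	8	11
cerebrovascular_disease	no	43	35	51
family_history	yes	10	7	13
family_history	no	47	36	49
apoe	carrier	27	21	14
apoe	non_carrier	30	22	48
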