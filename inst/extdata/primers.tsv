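name	sequence	printed_length	printed_tm	printed_gc	snp
*4_F	CACATTTTCTACAACCATGGAGACC	25	72	44.0	CYP3A4*4
*4_R	TACCTGTCCCCACCAGATTCATTCT	25	74	48.0	CYP3A4*4
*18B_F	CCACGAGCAGTGTTCTCTCCTTC	23	72	56.5	CYP3A4*18B
*18B_R	AATAGAAAGCAGATGAACCAGAGCC	25	72	44.0	CYP3A4*18B
*22_F	GCATAGAGTCTGCAGTCAGGCAAT	24	70	47.8	CYP3A4*22
*22_R	GATGACAGGGTTTGTGACAGGGG	23	72	56.5	CYP3A4*22
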