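fragment	PEX5	PEX6	PEX12	PEX13	PEX14	PEX16	PEX19	PEX11B	PEX11G	FIS1	ABCD1	ABCD3	ACBD5	ALDH3A2	ECH1	FAR1	PXMP2	PXMP4
aa1-29	NA	0	0	0	0	0	0	0	NA	0	0	0	NA	0	NA	0	0	0
aa1-99	NA	1	0	0	0	0	0	0	NA	0	0	0	NA	0	NA	0	0	0
aa1-192	NA	1	0	0	0	0	0	0	NA	1	0	0	NA	0	NA	0	0	0
aa1-251	NA	1	0	0	0	0	0	0	NA	1	0	0	NA	0	NA	0	0	0
aa1-269	NA	1	0	0	0	0	0	0	NA	1	0	0	NA	0	NA	0	0	0
aa29-174	NA	1	0	0	0	0	0	0	NA	1	0	0	NA	0	NA	0	0	0
aa96-305	NA	0	1	1	1	1	1	1	NA	0	1	1	NA	1	NA	1	1	1
aa175-251	NA	0	0	0	0	0	0	0	NA	0	0	0	NA	0	NA	0	0	0
aa175-305	NA	0	1	1	1	1	1	1	NA	0	1	1	NA	1	NA	1	1	1
aa270-305	NA	0	0	0	0	0	1	0	NA	0	0	0	NA	0	NA	0	0	0
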