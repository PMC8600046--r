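protein_a	protein_b
PEX26	PEX5
PEX26	PEX12
PEX26	PEX16
PEX26	PEX11B
PEX26	PEX11G
PEX26	FIS1
PEX26	ABCD1
PEX26	ABCD3
PEX26	ACBD5
PEX26	ALDH3A2
PEX26	ECH1
PEX26	FAR1
PEX26	PXMP2
PEX26	PXMP4
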