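protein_a	protein_b
PEX26	PEX6
PEX26	PEX19
PEX26	PEX14
PEX26	PEX13
PEX13	PEX14
PEX7	PEX13
PEX7	PEX14
PEX5	PEX7
PEX5	PEX12
PEX10	PEX12
PEX2	PEX10
PEX2	PEX12
PEX5	PEX14
PEX12	PEX13
PEX5	PEX10
PEX7	PEX10
PEX6	PEX13
PEX1	PEX6
PEX1	PEX5
PEX1	PEX19
PEX5	PEX6
PEX19	PEX3
PEX3	PEX16
PEX3	PXMP2
PEX3	PXMP4
PEX19	PEX11A
PEX19	MFF
PEX19	ABCD2
PEX19	PEX2
PEX19	PEX10
PEX19	PEX13
PEX19	PEX14
PEX19	PEX11G
PEX19	FAR1
PEX14	PEX16
PEX11A	PEX11B
PEX11A	PEX11G
PEX11B	PEX11G
PEX11B	FIS1
PEX11G	FIS1
FIS1	DNM1L
FIS1	MFF
MFF	DNM1L
PEX11A	DNM1L
ABCD1	ABCD2
ABCD1	ABCD3
ABCD2	ABCD3
ABCD2	ACBD5
ALDH3A2	FAR1
PEX5	HAO2
PEX5	PIPOX
PEX5	PAOX
PEX5	PECR
PEX5	GSTK1
PEX5	EPHX2
ECH1	ACAA1
ECH1	PEX5
PEX7	PHYH
PEX7	AGPS
PEX7	ACAA1
TYSND1	PRDX5
TYSND1	HAO1
TYSND1	ACOX2
LONP2	TYSND1
GNPAT	FAR2
CRAT	CROT
DAO	DDO
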