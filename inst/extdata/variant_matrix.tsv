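variant_id	PEX5	PEX6	PEX12	PEX13	PEX14	PEX16	PEX19	PEX11B	PEX11G	FIS1	ABCD1	ABCD3	ACBD5	ALDH3A2	ECH1	FAR1	PXMP2	PXMP4
WT	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
p.Leu44Pro	1	0	1	1	1	0	1	0	1	1	1	0	0	1	1	0	1	1
p.Leu45Pro	1	0	1	1	1	0	1	0	1	1	1	0	0	1	1	0	1	1
p.Gly89Arg	1	0	1	1	1	0	1	0	1	1	0	0	0	0	1	0	1	1
p.Arg98Trp	1	0	1	1	1	0	1	0	1	1	0	0	0	0	1	0	1	1
p.Pro117Leu	1	0	0	0	1	0	1	0	0	1	0	0	0	1	1	0	1	1
p.Pro118Arg	1	0	1	1	1	0	1	0	1	1	0	0	0	1	1	0	1	1
p.Leu153Val	1	1	1	1	1	0	1	1	1	1	1	0	0	1	1	1	1	0
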