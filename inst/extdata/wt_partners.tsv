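partner	provenance
PEX5	novel
PEX6	curated
PEX12	novel
PEX13	curated
PEX14	curated
PEX16	novel
PEX19	curated
PEX11B	novel
PEX11G	novel
FIS1	novel
ABCD1	novel
ABCD3	novel
ACBD5	novel
ALDH3A2	novel
ECH1	novel
FAR1	novel
PXMP2	novel
PXMP4	novel
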