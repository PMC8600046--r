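partner	block
PEX5	matrix protein import
PEX6	matrix protein import
PEX12	matrix protein import
PEX13	matrix protein import
PEX14	matrix protein import
PEX16	membrane assembly
PEX19	membrane assembly
PEX11B	division and proliferation
PEX11G	division and proliferation
FIS1	division and proliferation
ABCD1	fatty acid metabolism
ABCD3	fatty acid metabolism
ACBD5	fatty acid metabolism
ALDH3A2	fatty acid metabolism
ECH1	fatty acid metabolism
FAR1	fatty acid metabolism
PXMP2	unknown
PXMP4	unknown
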