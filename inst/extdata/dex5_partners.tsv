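partner
ABCD3
ECH1
FIS1
PEX11G
PEX14
PEX19
PEX5
PEX6
PXMP2
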