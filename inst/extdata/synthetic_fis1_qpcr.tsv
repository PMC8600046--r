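sample_id	group	target_gene	target_ct	reference_gene	reference_ct	calibrator
ctrl_1	control	FIS1	23.95	ACTB	17	TRUE
ctrl_2	control	FIS1	24.15	ACTB	17.1	TRUE
ctrl_3	control	FIS1	24	ACTB	16.95	TRUE
gm17398_1	PEX26_deficient	FIS1	24.8	ACTB	17.3	FALSE
gm17398_2	PEX26_deficient	FIS1	25.6	ACTB	17.2	FALSE
gm17398_3	PEX26_deficient	FIS1	26.1	ACTB	17.1	FALSE
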