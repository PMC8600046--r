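variant_id	protein_amount_class	catalase_import_pct	pts1_import_pct	pts2_import_pct
WT	wt_like	100	100	100
p.Leu44Pro	reduced	40	50	40
p.Leu45Pro	reduced	30	40	40
p.Gly89Arg	reduced	0	10	10
p.Arg98Trp	reduced	10	20	10
p.Pro117Leu	reduced	0	0	0
p.Pro118Arg	reduced	20	30	30
p.Leu153Val	wt_like	60	70	70
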