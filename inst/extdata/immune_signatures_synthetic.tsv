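signature	gene
macrophages	g001
macrophages	g002
lymphocytes	g003
lymphocytes	g004
tgf_beta	g005
tgf_beta	g006
ifn_gamma	g007
ifn_gamma	g008
wound_healing	g009
wound_healing	g010
cd8_t_cells	g011
cd8_t_cells	g012
cytotoxicity	g013
cytotoxicity	g014
tfh_cells	g015
tfh_cells	g016
b_t_cooperation	g017
b_t_cooperation	g018
igg	g019
cd274	g020
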