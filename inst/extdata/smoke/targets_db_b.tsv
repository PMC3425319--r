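mirna_id	gene_symbol
rno-miR-sim-0004	GENE0058
rno-miR-sim-0004	GENE0168
rno-miR-sim-0011	GENE0079
rno-miR-sim-0011	GENE0115
rno-miR-sim-0013	GENE0092
rno-miR-sim-0013	GENE0176
rno-miR-sim-0015	GENE0058
rno-miR-sim-0015	GENE0176
rno-miR-sim-0018	GENE0013
rno-miR-sim-0018	GENE0057
rno-miR-sim-0018	GENE0157
rno-miR-sim-0018	GENE0186
rno-miR-sim-0028	GENE0087
rno-miR-sim-0032	GENE0057
rno-miR-sim-0032	GENE0108
rno-miR-sim-0037	GENE0054
rno-miR-sim-0037	GENE0095
rno-miR-sim-0037	GENE0142
rno-miR-sim-0037	GENE0162
rno-miR-sim-0038	GENE0142
rno-miR-sim-0038	GENE0184
rno-miR-sim-0043	GENE0057
rno-miR-sim-0043	GENE0078
rno-miR-sim-0045	GENE0124
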