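mirna_id	gene_symbol	context_percentile
rno-miR-sim-0004	GENE0058	61.5114329149947
rno-miR-sim-0004	GENE0103	85.9142968081869
rno-miR-sim-0004	GENE0168	51.315934502054
rno-miR-sim-0005	GENE0100	75.8230956271291
rno-miR-sim-0011	GENE0079	70.4624034115113
rno-miR-sim-0011	GENE0115	88.1431857473217
rno-miR-sim-0013	GENE0092	87.7404481754638
rno-miR-sim-0013	GENE0176	72.7926391758956
rno-miR-sim-0015	GENE0058	73.8254077732563
rno-miR-sim-0015	GENE0102	80.7065417175181
rno-miR-sim-0015	GENE0176	82.9055169713683
rno-miR-sim-0016	GENE0092	29.5013393042609
rno-miR-sim-0018	GENE0013	51.1107888072729
rno-miR-sim-0018	GENE0057	88.3402861771174
rno-miR-sim-0018	GENE0157	70.13363459846
rno-miR-sim-0018	GENE0186	64.2607881454751
rno-miR-sim-0032	GENE0057	87.4978806707077
rno-miR-sim-0032	GENE0108	73.1475528329611
rno-miR-sim-0037	GENE0054	56.9541760603897
rno-miR-sim-0037	GENE0095	68.2795990374871
rno-miR-sim-0037	GENE0142	84.7666554502212
rno-miR-sim-0037	GENE0162	99.4728611665778
rno-miR-sim-0038	GENE0184	53.3140467246994
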