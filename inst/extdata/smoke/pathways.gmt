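PW001	simulated pathway PW001	GENE0023	GENE0086	GENE0111	GENE0137	GENE0173
PW002	simulated pathway PW002	GENE0008	GENE0052	GENE0054	GENE0058	GENE0070	GENE0095	GENE0102	GENE0115	GENE0144	GENE0162	GENE0168	GENE0170
PW003	simulated pathway PW003	GENE0033	GENE0040	GENE0054	GENE0074	GENE0081	GENE0090	GENE0096	GENE0113	GENE0117	GENE0152	GENE0162	GENE0190	GENE0194
PW004	simulated pathway PW004	GENE0011	GENE0017	GENE0018	GENE0049	GENE0050	GENE0116	GENE0121	GENE0138	GENE0164	GENE0176	GENE0185	GENE0186
PW005	simulated pathway PW005	GENE0011	GENE0082	GENE0123	GENE0144	GENE0155	GENE0174
PW006	simulated pathway PW006	GENE0018	GENE0078	GENE0091	GENE0100	GENE0117	GENE0136	GENE0163	GENE0164	GENE0166	GENE0176	GENE0180	GENE0183	GENE0187	GENE0190	GENE0199
PW007	simulated pathway PW007	GENE0014	GENE0016	GENE0051	GENE0080	GENE0098	GENE0109	GENE0124	GENE0183
PW008	simulated pathway PW008	GENE0033	GENE0082	GENE0086	GENE0117	GENE0171	GENE0187
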