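rsid	effect_allele	other_allele	weight
snp1	A	G	0.00918481
snp2	A	G	0.00953807
snp3	A	G	0.00989133
snp4	A	G	0.0102446
snp5	A	G	0.0105979
snp6	A	G	0.0109511
snp7	A	G	0.0113044
snp8	A	G	0.0116576
snp9	A	G	0.0120109
snp10	A	G	0.0123642
snp11	A	G	0.0127174
snp12	A	G	0.0130707
snp13	A	G	0.013424
snp14	A	G	0.0137772
snp15	A	G	0.0141305
snp16	A	G	0.0144837
snp17	A	G	0.014837
snp18	A	G	0.0151903
snp19	A	G	0.0155435
snp20	A	G	0.0158968
snp21	A	G	0.01625
snp22	A	G	0.0166033
snp23	A	G	0.0169566
snp24	A	G	0.0173098
snp25	A	G	0.0176631
snp26	A	G	0.0180164
snp27	A	G	0.0183696
snp28	A	G	0.0187229
snp29	A	G	0.0190761
snp30	A	G	0.0194294
snp31	A	G	0.0197827
snp32	A	G	0.0201359
snp33	A	G	0.0204892
snp34	A	G	0.0208425
snp35	A	G	0.0211957
snp36	A	G	0.021549
snp37	A	G	0.0219022
snp38	A	G	0.0222555
snp39	A	G	0.0226088
snp40	A	G	0.022962
snp41	A	G	0.0233153
snp42	A	G	0.0236685
snp43	A	G	0.0240218
snp44	A	G	0.0243751
snp45	A	G	0.0247283
snp46	A	G	0.0250816
snp47	A	G	0.0254349
snp48	A	G	0.0257881
snp49	A	G	0.0261414
snp50	A	G	0.0264946
snp51	A	G	0.0268479
snp52	A	G	0.0272012
snp53	A	G	0.0275544
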