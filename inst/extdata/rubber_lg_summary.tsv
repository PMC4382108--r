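linkage_group	snps	positions	length_cm
LG1	733	116	168.79
LG2	636	117	214.19
LG3	651	132	256.32
LG4	319	60	156.38
LG5	845	132	270.55
LG6	475	98	184.77
LG7	702	131	241.11
LG8	816	155	269.57
LG9	759	136	251.89
LG10	1367	194	336.85
LG11	435	79	229.08
LG12	448	88	156.72
LG13	780	142	284.83
LG14	834	124	197.99
LG15	609	121	253.95
LG16	519	104	216.93
LG17	496	106	242.47
LG18	902	151	227.95
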