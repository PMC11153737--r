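task	k	f1	cbr
luad_stage	1	48.7420	NA
luad_stage	2	86.2510	37.5090
luad_stage	3	91.2557	5.0047
luad_stage	4	92.5050	1.2492
luad_stage	5	93.3089	0.8039
luad_stage	6	96.1537	2.8448
luad_stage	7	96.8517	0.6979
luad_stage	8	96.9067	0.0550
luad_stage	9	97.4935	0.5868
luad_stage	10	97.8804	0.3868
brca_stage	1	71.9124	NA
brca_stage	2	93.4443	21.5318
brca_stage	3	95.3618	1.9174
brca_stage	4	96.2117	0.8499
brca_stage	5	97.2808	1.0691
brca_stage	6	97.4655	0.1846
brca_stage	7	98.2629	0.7974
brca_stage	8	99.1047	0.8417
brca_stage	9	98.3727	-0.7319
brca_stage	10	99.0001	0.6273
luad_subtype	1	73.2800	NA
luad_subtype	2	91.3155	18.0354
luad_subtype	3	95.9758	4.1303
luad_subtype	4	96.8973	0.5300
luad_subtype	5	97.3499	0.9214
luad_subtype	6	97.7847	0.4526
luad_subtype	7	97.7847	0.4347
luad_subtype	8	97.7847	0
luad_subtype	9	97.7847	0
luad_subtype	10	98.2410	0.4563
brca_subtype	1	51.2668	NA
brca_subtype	2	81.9457	30.6788
brca_subtype	3	89.6415	7.6958
brca_subtype	4	93.2176	3.5760
brca_subtype	5	94.4989	1.2813
brca_subtype	6	96.4546	1.9557
brca_subtype	7	96.9095	0.4549
brca_subtype	8	97.3826	0.4731
brca_subtype	9	97.3919	0.0093
brca_subtype	10	97.7572	0.3652
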