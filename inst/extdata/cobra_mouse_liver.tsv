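mouse	sex	CabpIAP	IAP31	IAP44	IAP51	IAP77	IAP90	IAP110	IAP176	IAP182	IAP186	IAP195	IAP236	IAP281Y	IAP268	IAP506	IAP655	IAP1112	IAP1248	IAP1252	IAP1259	IAP1334
Mouse1	F	74	52	70	77	60	80	71	69	70	61	70	62		77	77	76	66	LOD	83	82	88
Mouse2	F	77	60	77	75	60	71	72	60	71	68	76	68		84	86	70	69	83	77	78	86
Mouse3	F	81	57	77	78	66	76	72	66	74	55	73	67		76	71	76	68	84	78	84	LOD
Mouse4	F	72	61	80	77	65	68	69	56	77	56	54	65		73	82	70	60	89	80	81	86
Mouse5	F	74	59	71	78	61	80	75	65	70	69	69	63		80	81	70	LOD	76	78	82	90
Mouse6	M	76	57	78	74	65	73	71	63	64	67	76	58	64	77	94	76	63	78	LOD	85	86
Mouse7	F	66	62	80	75	61	73	78	54	67	65	64	66		75	75	74	60	85	78	82	86
Mouse8	F	76	60	75	78	62	72	64	63	71	65	73	60		78	93	70	62	81	79	84	LOD
Mouse9	M	67	62	83	73	64	70	67	69	75	69	74	63	67	76	76	74	68	87	83	86	86
Mouse10	F	82	62	80	47	68	69	57	57	78	73	65	58		82	92	79	60	84	82	81	91
Mouse11	M	70	60	87	69	65	71	73	65	70	68	72	54	64	80	76	73	63	87	87	84	90
Mouse12	M	48	61	77	70	66	71	57	63	74	71	76	64	61	84	94	75	64	81	82	81	89
Mouse13	M	79	64	81	73	64	69	66	67	69	68	75	62	64	80	81	72	66	LOD	77	84	86
Mouse14	F	79	58	79	72	68	76	57	63	69	68	78	71		79	82	77	69	84	84	84	90
Mouse15	F	74	55	80	75	68	74	71	60	72	66	71	60		81	80	71	64	83	84	85	89
Mouse16	M	73	56	81	71	70	69	48	60	83	71	75	67	57	83	74	73	66	82	79	85	88
Mouse17	M	76	59	71	78	62	78	72	66	66	67	68	65	65	78	LOD	77	65	82	79	83	91
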