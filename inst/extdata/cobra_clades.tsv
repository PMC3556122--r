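locus	clade	clade_label	y_linked
CabpIAP	clade1	red	FALSE
IAP31	clade1	red	FALSE
IAP44	clade1	red	FALSE
IAP51	clade1	red	FALSE
IAP77	clade1	red	FALSE
IAP90	clade1	red	FALSE
IAP110	clade1	red	FALSE
IAP176	clade2	green	FALSE
IAP182	clade2	green	FALSE
IAP186	clade2	green	FALSE
IAP195	clade2	green	FALSE
IAP236	clade2	green	FALSE
IAP281Y	clade2	green	TRUE
IAP268	clade2	green	FALSE
IAP506	clade3	black	FALSE
IAP655	clade3	black	FALSE
IAP1112	clade3	black	FALSE
IAP1248	clade3	black	FALSE
IAP1252	clade3	black	FALSE
IAP1259	clade3	black	FALSE
IAP1334	clade3	black	FALSE
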