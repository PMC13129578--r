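cultivar	n_del	n_ins	n_bnd	n_inv	n_dup	n_hom	n_het
Satsuma mandarin	3944	1958	246	37	21	158	6048
Kunenbo	7218	3636	608	68	62	1819	9773
Kishu mikan	6882	3927	581	78	42	3755	7755
Mediterranean mandarin	7907	4651	744	82	77	6447	7014
Ponkan	8816	4505	899	92	90	6236	8166
Dancy tangerine	7336	3525	666	87	79	6108	5585
King Mandarin	8436	4672	828	91	74	4950	9151
Murcott tangor	8306	4058	783	85	85	6704	6613
Iyokan	10838	5423	976	118	98	6615	10838
Sweet orange	11810	6548	940	140	117	7489	12066
Hassaku	10818	5869	723	103	87	4354	13246
Grapefruit	12213	6523	905	139	92	8240	11632
Pummelo	10478	5778	668	98	85	5732	11375
Hyuganatsu	11960	8012	1012	130	103	7460	13757
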