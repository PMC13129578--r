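marker	Satsuma mandarin	Kunenbo	Kishu mikan	Mediterranean mandarin	Ponkan	Dancy tangerine	King mandarin	Murcott tangor	Iyokan	Sweet orange	Hassaku	Grapefruit	Pummelo	Hyuganatsu
Marker1	0/0	0/1	0/1	1/1	0/1	1/1	1/1	0/1	0/1	0/0	0/0	0/0	0/0	0/0
Marker2	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	1/1	0/1	0/0
Marker3	0/0	0/0	0/0	1/1	0/0	0/0	1/1	1/1	0/0	0/0	0/0	0/0	0/1	0/0
Marker4	0/0	0/1	0/1	0/0	0/0	1/1	1/1	1/1	1/1	0/0	0/0	0/0	1/1	1/1
Marker5	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/1	1/1	0/1	0/1
Marker6	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/1	0/0	0/1	0/1	0/1	1/1	0/1
Marker7	0/1	0/1	1/1	1/1	1/1	1/1	0/1	1/1	0/1	0/1	0/1	0/1	0/0	0/1
Marker8	0/0	0/1	0/0	0/1	0/1	0/0	1/1	1/1	1/1	1/1	0/1	1/1	1/1	1/1
Marker9	0/0	0/1	0/0	0/0	0/1	0/0	0/1	0/1	0/0	0/1	0/1	1/1	0/1	0/1
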