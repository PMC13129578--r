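chrom	n_sites	n_three_genotype
chr1	5773	1098
chr2	7111	2381
chr3	10056	3263
chr4	5633	1381
chr5	6821	1685
chr6	5683	1683
chr7	6329	2141
chr8	6863	2158
chr9	5714	1726
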