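key	value
genome_size_mb	372.92
n_sites_total	59983
n_del	29058
n_ins	24867
n_inv	545
n_dup	470
n_first_length_bin	12938
n_over_10kb	2896
n_three_genotype	17516
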