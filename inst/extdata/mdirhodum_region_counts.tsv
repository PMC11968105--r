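region	n_sites
intergenic	4356
five_prime_utr	342
intron	4515
cds_nonsynonymous	515
cds_synonymous	1485
three_prime_utr	466
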