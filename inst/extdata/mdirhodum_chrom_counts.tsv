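chrom	n_sites
chromosome-1	1557
chromosome-2	1397
chromosome-3	1472
chromosome-4	1300
chromosome-5	1257
chromosome-6	898
chromosome-7	1300
chromosome-8	1197
chromosome-9	1299
scaffold-30	1
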