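chr1	0	100000	telomere_p
chr1	24950000	25050000	centromere
chr1	49900000	50000000	telomere_q
chr2	0	100000	telomere_p
chr2	24950000	25050000	centromere
chr2	49900000	50000000	telomere_q
chr3	0	100000	telomere_p
chr3	24950000	25050000	centromere
chr3	49900000	50000000	telomere_q
chrX	0	100000	telomere_p
chrX	14950000	15050000	centromere
chrX	29900000	30000000	telomere_q
chrY	0	100000	telomere_p
chrY	4950000	5050000	centromere
chrY	9900000	10000000	telomere_q
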