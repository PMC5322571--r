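id	random_region
CA125_1	ACTAGCTCCGATCTTTCTTATCTAC
CA125_2	CACTCTTTCATTTTATTTATAATTAT
CA125_3	TTCAATATTACTTATCTTTTTTTTT
CA125_12	TGCCTTATTACTCTCTCCTGTTAAC
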