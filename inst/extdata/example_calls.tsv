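sample_id	program_id	chrom	start	end	state	n_markers
S1	PC	1	100000	159999	1	45
S1	PC	1	172000	179999	1	12
S1	PC	2	500000	739999	3	210
S1	PC	X	100000	200000	1	80
S1	AGC	1	101000	161999	1	50
S1	AGC	2	498000	742999	3	212
S2	PC	1	100500	160499	1	46
S2	PC	7	3000000	3049999	4	55
S2	AGC	1	100900	160899	1	44
S2	AGC	12	9000000	9000900	0	9
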