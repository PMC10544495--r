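name	length	centromere	is_autosome
chr1	248956422	123400000	TRUE
chr2	242193529	93900000	TRUE
chr3	198295559	90900000	TRUE
chr4	190214555	50000000	TRUE
chr5	181538259	48800000	TRUE
chr6	170805979	59800000	TRUE
chr7	159345973	60100000	TRUE
chr8	145138636	45200000	TRUE
chr9	138394717	43000000	TRUE
chr10	133797422	39800000	TRUE
chr11	135086622	53400000	TRUE
chr12	133275309	35500000	TRUE
chr13	114364328	17700000	TRUE
chr14	107043718	17200000	TRUE
chr15	101991189	19000000	TRUE
chr16	90338345	36800000	TRUE
chr17	83257441	25100000	TRUE
chr18	80373285	18500000	TRUE
chr19	58617616	26200000	TRUE
chr20	64444167	28100000	TRUE
chr21	46709983	12000000	TRUE
chr22	50818468	15000000	TRUE
chrX	156040895	61000000	FALSE
chrY	57227415	10400000	FALSE
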