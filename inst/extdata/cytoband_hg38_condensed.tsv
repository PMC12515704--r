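chr1	0	121700000	p	gneg
chr1	121700000	123400000	p11.1	acen
chr1	123400000	125100000	q11.1	acen
chr1	125100000	248956422	q	gneg
chr2	0	91800000	p	gneg
chr2	91800000	93900000	p11.1	acen
chr2	93900000	96000000	q11.1	acen
chr2	96000000	242193529	q	gneg
chr3	0	87800000	p	gneg
chr3	87800000	90900000	p11.1	acen
chr3	90900000	94000000	q11.1	acen
chr3	94000000	198295559	q	gneg
chr4	0	48200000	p	gneg
chr4	48200000	50000000	p11.1	acen
chr4	50000000	51800000	q11.1	acen
chr4	51800000	190214555	q	gneg
chr5	0	46100000	p	gneg
chr5	46100000	48400000	p11.1	acen
chr5	48400000	50700000	q11.1	acen
chr5	50700000	181538259	q	gneg
chr6	0	58500000	p	gneg
chr6	58500000	60550000	p11.1	acen
chr6	60550000	62600000	q11.1	acen
chr6	62600000	170805979	q	gneg
chr7	0	58100000	p	gneg
chr7	58100000	60100000	p11.1	acen
chr7	60100000	62100000	q11.1	acen
chr7	62100000	159345973	q	gneg
chr8	0	43200000	p	gneg
chr8	43200000	45200000	p11.1	acen
chr8	45200000	47200000	q11.1	acen
chr8	47200000	145138636	q	gneg
chr9	0	42200000	p	gneg
chr9	42200000	43850000	p11.1	acen
chr9	43850000	45500000	q11.1	acen
chr9	45500000	138394717	q	gneg
chr10	0	38000000	p	gneg
chr10	38000000	39800000	p11.1	acen
chr10	39800000	41600000	q11.1	acen
chr10	41600000	133797422	q	gneg
chr11	0	51000000	p	gneg
chr11	51000000	53400000	p11.1	acen
chr11	53400000	55800000	q11.1	acen
chr11	55800000	135086622	q	gneg
chr12	0	33200000	p	gneg
chr12	33200000	35500000	p11.1	acen
chr12	35500000	37800000	q11.1	acen
chr12	37800000	133275309	q	gneg
chr13	0	16500000	p	gvar
chr13	16500000	17700000	p11.1	acen
chr13	17700000	18900000	q11.1	acen
chr13	18900000	114364328	q	gneg
chr14	0	16100000	p	gvar
chr14	16100000	17150000	p11.1	acen
chr14	17150000	18200000	q11.1	acen
chr14	18200000	107043718	q	gneg
chr15	0	17500000	p	gvar
chr15	17500000	19000000	p11.1	acen
chr15	19000000	20500000	q11.1	acen
chr15	20500000	101991189	q	gneg
chr16	0	35300000	p	gneg
chr16	35300000	36850000	p11.1	acen
chr16	36850000	38400000	q11.1	acen
chr16	38400000	90338345	q	gneg
chr17	0	22700000	p	gneg
chr17	22700000	25050000	p11.1	acen
chr17	25050000	27400000	q11.1	acen
chr17	27400000	83257441	q	gneg
chr18	0	15400000	p	gneg
chr18	15400000	18450000	p11.1	acen
chr18	18450000	21500000	q11.1	acen
chr18	21500000	80373285	q	gneg
chr19	0	24200000	p	gneg
chr19	24200000	26150000	p11.1	acen
chr19	26150000	28100000	q11.1	acen
chr19	28100000	58617616	q	gneg
chr20	0	25700000	p	gneg
chr20	25700000	28050000	p11.1	acen
chr20	28050000	30400000	q11.1	acen
chr20	30400000	64444167	q	gneg
chr21	0	10900000	p	gvar
chr21	10900000	11950000	p11.1	acen
chr21	11950000	13000000	q11.1	acen
chr21	13000000	46709983	q	gneg
chr22	0	13700000	p	gvar
chr22	13700000	15550000	p11.1	acen
chr22	15550000	17400000	q11.1	acen
chr22	17400000	50818468	q	gneg
chrX	0	58100000	p	gneg
chrX	58100000	60950000	p11.1	acen
chrX	60950000	63800000	q11.1	acen
chrX	63800000	156040895	q	gneg
chrY	0	10300000	p	gneg
chrY	10300000	10450000	p11.1	acen
chrY	10450000	10600000	q11.1	acen
chrY	10600000	57227415	q	gneg
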