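name	sequence	orientation	ecoli_start	ecoli_end	pair
68f	TNANACATGCAAGTCGRRCG	forward	49	68	68f/518r
518r	WTTACCGCGGCTGCTGG	reverse	518	534	68f/518r
341f	CCTACGGGNGGCWGCAG	forward	341	357	341f/785r
785r	GACTACHVGGGTATCTAATCC	reverse	785	805	341f/785r
799f	AACMGGATTAGATACCCKG	forward	781	799	799f/1193r
1193r	ACGTCATCCCCACCTTCC	reverse	1177	1194	799f/1193r
967f	CAACGCGAAGAACCTTACC	forward	967	985	967f/1391r
1391r	GACGGGCGGTGWGTRCA	reverse	1391	1407	967f/1391r
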