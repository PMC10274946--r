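motif	spacer_min	spacer_max	bin
GG	13	15	0
GG	11	12	1
GG	3	4	2
GG	5	10	3
GGCGG	13	15	4
GGGGG	13	15	4
GGTGG	13	15	4
GGCGG	11	12	5
GGGGG	11	12	5
GGTGG	11	12	5
GGCGG	3	4	6
GGGGG	3	4	6
GGTGG	3	4	6
GGCGG	5	10	7
GGGGG	5	10	7
GGTGG	5	10	7
AGG	13	15	8
GAG	13	15	8
GGA	13	15	8
AGG	11	12	9
GAG	11	12	9
GGA	11	12	9
AGG	3	4	10
GAG	3	4	10
GGA	3	4	10
AGG	5	10	11
GAG	5	10	11
GGA	5	10	11
AGGA	13	15	12
GAGG	13	15	12
GGAG	13	15	12
AGGA	11	12	13
GAGG	11	12	13
GGAG	11	12	13
AGGA	3	4	14
GAGG	3	4	14
GGAG	3	4	14
AGGA	5	10	15
GAGG	5	10	15
GGAG	5	10	15
AGGAG	13	15	16
GGAGG	13	15	16
AGGAG	11	12	17
GGAGG	11	12	17
AGGAG	3	4	18
GGAGG	3	4	18
AGGAG	5	10	19
GGAGG	5	10	19
AGAAGG	13	15	20
AGCAGG	13	15	20
AGGCGG	13	15	20
AGGGGG	13	15	20
AGGTGG	13	15	20
AGTAGG	13	15	20
AGAAGG	11	12	21
AGCAGG	11	12	21
AGGCGG	11	12	21
AGGGGG	11	12	21
AGGTGG	11	12	21
AGTAGG	11	12	21
AGAAGG	3	4	22
AGCAGG	3	4	22
AGGCGG	3	4	22
AGGGGG	3	4	22
AGGTGG	3	4	22
AGTAGG	3	4	22
AGAAGG	5	10	23
AGCAGG	5	10	23
AGGCGG	5	10	23
AGGGGG	5	10	23
AGGTGG	5	10	23
AGTAGG	5	10	23
AGGAGG	13	15	24
AGGAGG	11	12	25
AGGAGG	3	4	26
AGGAGG	5	10	27
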