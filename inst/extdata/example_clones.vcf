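##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	C01_A	C01_B	C02	C03	C04	C05	C06
SPA1	3169	.	C	T	101.56350	.	.	GT:DP	0/0:34	0/0:35	0/0:26	0/0:44	1/1:40	0/0:38	0/0:40
SPA1	3359	.	G	A	112.46248	.	.	GT:DP	0/0:27	0/0:36	0/0:30	0/0:40	0/0:35	0/0:33	1/1:42
SPA1	4561	.	G	T	232.85412	.	.	GT:DP	1/1:34	1/1:37	1/1:45	1/1:25	0/0:29	0/0:43	0/0:42
SPA1	7065	.	C	A	111.09900	.	.	GT:DP	0/0:49	0/0:40	0/0:32	0/0:48	1/1:37	1/1:35	1/1:28
SPA1	7149	.	A	G	102.77294	.	.	GT:DP	1/1:35	1/1:33	1/1:33	1/1:30	0/0:39	0/0:36	0/0:42
SPA1	12189	.	A	C	146.60095	.	.	GT:DP	1/1:38	1/1:31	1/1:34	0/0:24	0/0:37	0/0:29	0/0:37
SPA1	16898	.	A	G	108.71087	.	.	GT:DP	1/1:30	1/1:41	1/1:32	0/0:30	0/0:25	0/0:37	0/0:36
SPA1	30592	.	A	G	154.15778	.	.	GT:DP	1/1:32	1/1:33	1/1:29	0/0:34	0/0:33	0/0:32	0/0:31
SPA1	31749	.	A	T	194.64964	.	.	GT:DP	0/0:34	0/0:38	1/1:38	0/0:36	0/0:41	0/0:37	0/0:35
SPA1	43118	.	C	G	114.42738	.	.	GT:DP	1/1:33	1/1:15	0/0:39	0/0:34	0/0:35	0/0:35	0/0:25
SPA2	11696	.	C	T	99.05130	.	.	GT:DP	0/0:34	0/0:39	0/0:35	0/0:28	0/0:37	1/1:37	1/1:27
SPA2	15030	.	C	G	184.81537	.	.	GT:DP	1/1:29	1/1:37	1/1:36	1/1:36	0/0:29	0/0:31	0/0:39
SPA2	17519	.	C	T	94.43177	.	.	GT:DP	1/1:41	1/1:34	1/1:40	1/1:39	0/0:32	0/0:31	0/0:38
SPA2	33258	.	A	G	160.36388	.	.	GT:DP	0/0:33	0/0:46	0/0:38	0/0:41	0/0:38	1/1:39	1/1:38
SPA2	42038	.	T	A	206.68062	.	.	GT:DP	0/0:42	0/0:33	0/0:44	0/0:32	1/1:33	0/0:27	0/0:27
SPA2	44885	.	T	A	112.26215	.	.	GT:DP	1/1:37	1/1:40	1/1:34	0/0:23	0/0:35	0/0:36	0/0:38
SPA2	45709	.	A	C	108.84530	.	.	GT:DP	0/0:47	0/0:31	0/0:39	1/1:32	0/0:35	0/0:26	0/0:25
SPA2	46665	.	T	A	111.71495	.	.	GT:DP	1/1:50	1/1:40	1/1:27	0/0:29	0/0:30	0/0:41	0/0:39
SPA2	48998	.	C	G	163.34066	.	.	GT:DP	0/0:23	0/0:37	0/0:36	1/1:36	0/0:43	0/0:26	0/0:27
SPE1	3110	.	A	T	127.37513	.	.	GT:DP	0/0:29	0/0:44	0/0:28	0/0:36	1/1:34	0/0:32	0/0:37
SPE1	4189	.	T	C	128.35654	.	.	GT:DP	0/0:37	0/0:25	0/0:38	0/0:42	1/1:40	0/0:36	0/0:34
SPE1	19240	.	C	T	105.55628	.	.	GT:DP	1/1:23	1/1:42	1/1:41	1/1:38	0/0:36	0/0:37	0/0:41
SPE1	27984	.	C	T	211.83271	.	.	GT:DP	0/0:33	0/0:39	0/0:24	1/1:32	0/0:36	0/0:42	0/0:24
SPE1	33576	.	C	G	131.90585	.	.	GT:DP	1/1:37	1/1:21	1/1:28	0/0:25	0/0:30	0/0:34	0/0:34
SPE1	33670	.	G	A	138.69348	.	.	GT:DP	0/0:33	0/0:44	0/0:30	0/0:34	1/1:42	0/0:32	0/0:35
SPE2	6418	.	G	A	126.79111	.	.	GT:DP	0/0:28	0/0:37	0/0:34	0/0:35	0/0:35	1/1:37	1/1:43
SPE2	9625	.	T	C	133.57771	.	.	GT:DP	1/1:35	1/1:28	1/1:28	0/0:35	0/0:36	0/0:35	0/0:39
SPE2	10225	.	C	T	108.88211	.	.	GT:DP	0/0:41	0/0:37	0/0:29	0/0:36	0/0:40	0/0:26	1/1:29
SPE2	10701	.	G	T	111.65069	.	.	GT:DP	1/1:41	1/1:25	1/1:28	1/1:45	0/0:40	0/0:36	0/0:28
SPE2	13393	.	A	T	107.46100	.	.	GT:DP	0/0:33	0/0:35	0/0:26	0/0:36	0/0:23	1/1:27	1/1:32
SPE2	14135	.	G	A	129.36307	.	.	GT:DP	0/0:40	0/0:30	0/0:41	0/0:31	0/0:24	0/0:35	1/1:40
SPE2	38127	.	G	A	154.83378	.	.	GT:DP	0/0:48	0/0:31	0/0:24	0/0:40	0/0:30	0/0:32	1/1:31
SPE2	44703	.	C	G	91.09624	.	.	GT:DP	0/0:30	0/0:29	0/0:25	0/0:32	0/0:32	0/0:44	1/1:32
SPE2	48067	.	G	A	188.79496	.	.	GT:DP	0/0:35	0/0:24	0/0:27	0/0:38	1/1:34	1/1:31	1/1:33
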