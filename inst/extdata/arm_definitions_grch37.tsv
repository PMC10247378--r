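chrom	arm	start	end
1	p	0	125000000
1	q	125000000	249250621
2	p	0	93300000
2	q	93300000	243199373
3	p	0	91000000
3	q	91000000	198022430
4	p	0	50400000
4	q	50400000	191154276
5	p	0	48400000
5	q	48400000	180915260
6	p	0	61000000
6	q	61000000	171115067
7	p	0	59900000
7	q	59900000	159138663
8	p	0	45600000
8	q	45600000	146364022
9	p	0	49000000
9	q	49000000	141213431
10	p	0	40200000
10	q	40200000	135534747
11	p	0	53700000
11	q	53700000	135006516
12	p	0	35800000
12	q	35800000	133851895
13	q	17900000	115169878
14	q	17600000	107349540
15	q	19000000	102531392
16	p	0	36600000
16	q	36600000	90354753
17	p	0	24000000
17	q	24000000	81195210
18	p	0	17200000
18	q	17200000	78077248
19	p	0	26500000
19	q	26500000	59128983
20	p	0	27500000
20	q	27500000	63025520
21	q	13200000	48129895
22	q	14700000	51304566
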