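element	isotope	mass	abundance
H	1	1.0078250319	0.999885
H	2	2.0141017781	0.000115
C	12	12.0	0.9893
C	13	13.0033548351	0.0107
N	14	14.0030740052	0.99636
N	15	15.0001088989	0.00364
O	16	15.9949146221	0.99757
O	17	16.9991317565	0.00038
O	18	17.9991596129	0.00205
Si	28	27.9769265327	0.92223
Si	29	28.9764946653	0.04685
Si	30	29.9737701370	0.03092
P	31	30.9737615120	1.0
S	32	31.9720706912	0.9499
S	33	32.9714585898	0.0075
S	34	33.9678668311	0.0425
S	36	35.9670808800	0.0001
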