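chrom	start	end	type	length
1A	4848463	4848525	Deletion	62
1B	9587887	9587888	Insertion	82
1A	11762865	11762883	Deletion	18
1A	45518693	45518694	Tandem_contraction	160
1A	54185700	54185920	Deletion	220
1A	64269721	64269722	Tandem_contraction	88
1A	65578543	65578607	Deletion	64
1A	67965609	67965610	Insertion	278
1A	72511229	72511230	Insertion	59
2A	74006937	74006938	Insertion	126
1A	79652895	79652951	Deletion	56
2A	86282182	86282252	Deletion	70
1A	86891637	86891638	Insertion	467
1A	88108434	88108646	Deletion	212
1A	88451390	88451411	Deletion	21
1A	95226254	95226310	Deletion	56
2A	112379724	112379725	Insertion	40
1A	112548902	112548903	Insertion	76
1A	115615546	115615547	Insertion	130
1A	117121456	117121457	Insertion	123
1A	129011982	129011983	Insertion	11
2A	133576766	133576767	Insertion	35
1B	133999123	133999124	Repeat_expansion	16
1A	145087023	145087053	Deletion	30
1B	146359974	146359986	Deletion	12
1B	155174057	155174058	Insertion	50
1A	185746115	185746116	Insertion	345
1A	186069254	186069255	Repeat_expansion	47
1A	190172041	190172042	Insertion	32
1A	206895723	206895724	Insertion	111
1A	211951828	211951874	Deletion	46
2A	214441114	214441115	Insertion	565
1A	218633418	218633419	Insertion	46
2A	222485765	222485770	Deletion	5
1B	223528024	223528025	Insertion	16
1A	258584032	258584206	Deletion	174
1A	264877931	264877947	Deletion	16
1A	279138923	279138924	Repeat_expansion	24
1A	294786347	294786385	Deletion	38
1A	297981926	297981927	Tandem_contraction	8
1A	298481668	298481669	Repeat_expansion	115
2A	300815288	300815379	Deletion	91
1A	313675213	313675234	Deletion	21
1B	336001977	336001978	Tandem_contraction	10
1A	338553654	338553716	Deletion	62
1A	342358391	342358392	Tandem_contraction	144
1B	345854064	345854065	Insertion	64
2A	352668902	352669185	Deletion	283
1A	377761468	377761781	Deletion	313
1A	382776938	382776939	Insertion	15
1A	385262842	385262936	Deletion	94
1A	396395834	396395835	Repeat_expansion	47
1A	398540081	398540230	Deletion	149
2A	403045954	403045955	Tandem_contraction	166
1A	413229738	413229739	Insertion	37
1B	417122532	417122533	Repeat_expansion	65
1A	427023308	427023309	Insertion	170
1A	429067405	429067499	Deletion	94
1B	430590947	430590948	Tandem_contraction	8
1A	432303822	432303823	Insertion	68
1B	435409648	435409649	Tandem_contraction	108
2A	440944211	440944212	Insertion	357
1B	471741454	471741538	Deletion	84
1A	480654419	480654557	Deletion	138
1A	495858460	495858493	Deletion	33
1A	495994931	495994932	Repeat_expansion	28
1B	498473042	498473087	Deletion	45
1A	519230362	519230363	Tandem_contraction	83
1A	520451487	520451488	Insertion	30
2A	521271117	521271118	Repeat_expansion	308
1A	525884825	525884826	Insertion	9
1A	532917754	532917787	Deletion	33
1B	536146010	536146278	Deletion	268
2A	544485686	544485918	Deletion	232
2A	557948229	557948339	Deletion	110
1B	565626865	565626866	Insertion	27
1A	574911799	574911864	Deletion	65
1A	584821604	584821605	Insertion	105
1A	587480921	587481520	Deletion	599
1A	595900694	595900870	Deletion	176
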