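# SYNTHETIC stand-in insertion table: a constructed reference set of 73
# mapped promoter-trap insertions whose aggregate properties match the
# published screen summaries (fraction in 5-prime-UTR introns, first-intron
# preference, distance spread). Not real data.
insertion_id	line_id	scaffold	position	element_strand	construct	feature_class	intron_ordinal	n_introns	distance_to_orf_start
S2_001	F2A	SYN00013	3857636	+	non_IRES	five_prime_utr_intron	1	2	183
S2_002	F1C	SYN00031	4535614	-	non_IRES	five_prime_utr_intron	1	6	328
S2_003	F1D	SYN00001	3588246	-	non_IRES	five_prime_utr_intron	1	5	473
S2_004	M1	SYN00017	868379	+	non_IRES	five_prime_utr_intron	1	3	617
S2_005	F1C	SYN00033	3428930	+	IRES	five_prime_utr_intron	1	3	762
S2_006	M1	SYN00028	656264	+	IRES	five_prime_utr_intron	1	4	907
S2_007	M1	SYN00002	4317106	-	IRES	five_prime_utr_intron	1	2	1052
S2_008	F1C	SYN00031	2235946	+	non_IRES	five_prime_utr_intron	1	2	1197
S2_009	F1D	SYN00008	2995246	-	IRES	five_prime_utr_intron	1	4	1342
S2_010	F2A	SYN00016	3475495	+	non_IRES	five_prime_utr_intron	1	5	1486
S2_011	F1D	SYN00003	2499075	+	IRES	five_prime_utr_intron	1	6	1631
S2_012	F1D	SYN00037	4867849	+	non_IRES	five_prime_utr_intron	1	6	1776
S2_013	F1C	SYN00013	2124140	+	non_IRES	five_prime_utr_intron	1	6	1921
S2_014	F2A	SYN00012	2331708	-	IRES	five_prime_utr_intron	1	5	2066
S2_015	F1C	SYN00001	1450427	+	IRES	five_prime_utr_intron	1	3	2210
S2_016	M1	SYN00030	4174348	-	IRES	five_prime_utr_intron	1	5	2355
S2_017	F1C	SYN00031	433787	-	IRES	five_prime_utr_intron	1	4	2500
S2_018	F2A	SYN00037	317358	+	non_IRES	five_prime_utr_intron	1	3	2600
S2_019	F1C	SYN00006	2075361	-	IRES	five_prime_utr_intron	1	2	2800
S2_020	F2A	SYN00016	2529692	-	non_IRES	five_prime_utr_intron	1	3	3330
S2_021	M1	SYN00010	3510545	+	non_IRES	five_prime_utr_intron	1	4	3961
S2_022	F1C	SYN00007	1786002	+	IRES	five_prime_utr_intron	1	3	4711
S2_023	F1C	SYN00009	2149758	+	IRES	five_prime_utr_intron	1	5	5603
S2_024	F1D	SYN00025	3492761	-	non_IRES	five_prime_utr_intron	1	5	6663
S2_025	F1D	SYN00003	4641154	+	non_IRES	five_prime_utr_intron	1	3	7925
S2_026	F2B	SYN00018	1628539	-	IRES	five_prime_utr_intron	1	6	9426
S2_027	F2B	SYN00028	4820824	+	non_IRES	five_prime_utr_intron	1	5	11210
S2_028	F1D	SYN00015	1206366	-	IRES	five_prime_utr_intron	1	6	13333
S2_029	F1D	SYN00029	3017734	+	IRES	five_prime_utr_intron	1	5	15857
S2_030	F2B	SYN00020	166821	+	non_IRES	five_prime_utr_intron	1	3	18860
S2_031	F2B	SYN00025	3996451	+	IRES	five_prime_utr_intron	1	3	22431
S2_032	F1D	SYN00016	2704497	-	non_IRES	five_prime_utr_intron	1	4	26678
S2_033	F1C	SYN00024	2981920	+	non_IRES	five_prime_utr_intron	1	2	31729
S2_034	F1C	SYN00033	2401468	-	non_IRES	five_prime_utr_intron	1	6	37737
S2_035	F1D	SYN00038	3260354	-	non_IRES	five_prime_utr_intron	1	3	44882
S2_036	F1D	SYN00022	3105457	+	IRES	coding_intron	1	3	10513
S2_037	F1C	SYN00026	3800659	+	IRES	coding_intron	1	7	6682
S2_038	F2B	SYN00020	4000758	-	non_IRES	coding_intron	1	7	-1339
S2_039	F2A	SYN00037	2112637	-	IRES	coding_intron	1	3	2301
S2_040	M1	SYN00015	1221717	-	IRES	coding_intron	1	5	6879
S2_041	F1D	SYN00021	1921401	+	IRES	coding_intron	1	4	4383
S2_042	F2B	SYN00034	2442392	-	non_IRES	coding_intron	1	7	4525
S2_043	F1D	SYN00025	3652186	+	IRES	coding_intron	1	6	-3657
S2_044	F2A	SYN00038	396846	-	IRES	coding_intron	1	3	-3669
S2_045	F1D	SYN00001	4476317	-	IRES	coding_intron	1	8	-221
S2_046	F1C	SYN00014	4153849	-	IRES	coding_intron	1	7	10849
S2_047	F2B	SYN00011	3058640	+	non_IRES	coding_intron	1	3	11252
S2_048	M1	SYN00028	2641561	-	non_IRES	coding_intron	1	3	6797
S2_049	F1D	SYN00018	3178715	+	non_IRES	coding_intron	1	6	6665
S2_050	F1C	SYN00034	1439248	+	IRES	coding_intron	1	2	2715
S2_051	F1C	SYN00036	249170	+	IRES	coding_intron	1	2	-7955
S2_052	M1	SYN00020	3813188	+	non_IRES	coding_intron	2	8	4179
S2_053	F2A	SYN00015	2466188	-	IRES	coding_intron	2	5	8736
S2_054	F2B	SYN00007	3867220	+	non_IRES	coding_intron	2	6	7030
S2_055	F1D	SYN00027	2748877	-	non_IRES	coding_intron	2	3	1055
S2_056	F1C	SYN00030	1282993	-	IRES	coding_intron	3	3	2716
S2_057	M1	SYN00005	1302168	-	non_IRES	coding_intron	5	6	2748
S2_058	F2A	SYN00022	1747901	+	non_IRES	coding_intron	3	5	-7972
S2_059	F1D	SYN00020	2995986	-	IRES	coding_intron	3	5	-887
S2_060	M1	SYN00011	1146777	-	IRES	coding_intron	2	2	4243
S2_061	F2A	SYN00028	3424884	+	non_IRES	coding_intron	5	5	8579
S2_062	F2B	SYN00038	4592044	-	IRES	coding_intron	4	4	-866
S2_063	F1D	SYN00009	2569062	+	non_IRES	coding_intron	5	6	213
S2_064	F1C	SYN00023	4973529	-	non_IRES	coding_intron	4	6	3470
S2_065	F2A	SYN00026	3548488	+	non_IRES	coding_intron	5	5	3794
S2_066	F2A	SYN00011	1727473	-	IRES	exon	NA	NA	757
S2_067	F2B	SYN00019	943616	+	non_IRES	exon	NA	NA	-1840
S2_068	F2B	SYN00028	3955810	+	non_IRES	exon	NA	NA	2354
S2_069	F2B	SYN00021	664476	-	non_IRES	exon	NA	NA	2701
S2_070	F2A	SYN00036	4037237	+	non_IRES	exon	NA	NA	-3132
S2_071	F1C	SYN00022	30746	+	IRES	exon	NA	NA	796
S2_072	F1C	SYN00025	4827915	+	IRES	exon	NA	NA	2229
S2_073	F1C	SYN00030	1048066	+	IRES	exon	NA	NA	-172
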