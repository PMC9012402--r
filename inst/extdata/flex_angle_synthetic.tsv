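# Synthetic statistics-derived local-term table (generic shape, not a
# published calibration).  Schema: uniform angle grid (rad), energy
# (kcal/mol).  Substitute residue-specific tables with the same schema.
theta	E
0.35	4.91863227
0.375	4.95760224
0.4	4.99349249
0.425	5.02638589
0.45	5.05613265
0.475	5.08224518
0.5	5.10372824
0.525	5.11883272
0.55	5.12474948
0.575	5.11733398
0.6	5.09108957
0.625	5.03977128
0.65	4.95786345
0.675	4.84256977
0.7	4.69516734
0.725	4.52069315
0.75	4.32620407
0.775	4.11883911
0.8	3.90461677
0.825	3.68807129
0.85	3.47239085
0.875	3.25972831
0.9	3.05150658
0.925	2.84865779
0.95	2.65179233
0.975	2.46131213
1	2.27748445
1.025	2.10048934
1.05	1.93045003
1.075	1.76745237
1.1	1.61155728
1.125	1.46280882
1.15	1.32123939
1.175	1.18687315
1.2	1.05972820
1.225	0.93981797
1.25	0.82715215
1.275	0.72173715
1.3	0.62357628
1.325	0.53266980
1.35	0.44901459
1.375	0.37260373
1.4	0.30342576
1.425	0.24146368
1.45	0.18669354
1.475	0.13908261
1.5	0.09858687
1.525	0.06514778
1.55	0.03868802
1.575	0.01910586
1.6	0.00626796
1.625	0.00000000
1.65	0.00007491
1.675	0.00619799
1.7	0.01798891
1.725	0.03496046
1.75	0.05649491
1.775	0.08182006
1.8	0.10998892
1.825	0.13986953
1.85	0.17015445
1.875	0.19940064
1.9	0.22610935
1.925	0.24884795
1.95	0.26640221
1.975	0.27793075
2	0.28308248
2.025	0.28204171
2.05	0.27548623
2.075	0.26447250
2.1	0.25028267
2.125	0.23427295
2.15	0.21775165
2.175	0.20189906
2.2	0.18772706
2.225	0.17606933
2.25	0.16759117
2.275	0.16280942
2.3	0.16211602
2.325	0.16580109
2.35	0.17407352
2.375	0.18707824
2.4	0.20491015
2.425	0.22762497
2.45	0.25524745
2.475	0.28777743
2.5	0.32519411
2.525	0.36745881
2.55	0.41451668
2.575	0.46629727
2.6	0.52271427
2.625	0.58366441
2.65	0.64902541
2.675	0.71865305
2.7	0.79237701
2.725	0.86999521
2.75	0.95126632
2.775	1.03589941
2.8	1.12354004
2.825	1.21375074
2.85	1.30598350
2.875	1.39953984
2.9	1.49351122
2.925	1.58668710
2.95	1.67740723
2.975	1.76331170
3	1.84089021
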