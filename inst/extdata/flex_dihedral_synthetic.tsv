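# Synthetic statistics-derived local-term table (generic shape, not a
# published calibration).  Schema: uniform angle grid (rad), energy
# (kcal/mol).  Substitute residue-specific tables with the same schema.
phi	E
-3.14159265359	0.75413996
-3.09795942229	0.73638587
-3.05432619099	0.71671090
-3.01069295969	0.69542197
-2.96705972839	0.67285852
-2.92342649709	0.64938416
-2.87979326579	0.62537791
-2.83616003449	0.60122562
-2.79252680319	0.57731189
-2.74889357189	0.55401280
-2.70526034059	0.53168954
-2.66162710929	0.51068298
-2.61799387799	0.49130928
-2.57436064669	0.47385626
-2.53072741539	0.45858062
-2.48709418409	0.44570578
-2.44346095279	0.43542030
-2.39982772149	0.42787671
-2.35619449019	0.42319078
-2.31256125889	0.42144100
-2.26892802759	0.42266844
-2.22529479629	0.42687668
-2.18166156499	0.43403209
-2.13802833369	0.44406419
-2.09439510239	0.45686627
-2.05076187109	0.47229625
-2.00712863979	0.49017769
-1.96349540849	0.51030121
-1.91986217719	0.53242617
-1.87622894589	0.55628280
-1.83259571459	0.58157478
-1.78896248329	0.60798238
-1.74532925199	0.63516622
-1.70169602069	0.66277174
-1.65806278939	0.69043425
-1.61442955809	0.71778487
-1.57079632679	0.74445687
-1.5271630955	0.77009260
-1.4835298642	0.79435068
-1.4398966329	0.81691305
-1.3962634016	0.83749175
-1.3526301703	0.85583479
-1.308996939	0.87173101
-1.2653637077	0.88501342
-1.2217304764	0.89556086
-1.1780972451	0.90329803
-1.1344640138	0.90819369
-1.0908307825	0.91025750
-1.0471975512	0.90953563
-1.0035643199	0.90610552
-0.959931088597	0.90007028
-0.916297857297	0.89155297
-0.872664625997	0.88069114
-0.829031394697	0.86763184
-0.785398163397	0.85252726
-0.741764932098	0.83553111
-0.698131700798	0.81679570
-0.654498469498	0.79646976
-0.610865238198	0.77469688
-0.567232006898	0.75161457
-0.523598775598	0.72735373
-0.479965544298	0.70203864
-0.436332312999	0.67578718
-0.392699081699	0.64871144
-0.349065850399	0.62091842
-0.305432619099	0.59251103
-0.261799387799	0.56358914
-0.218166156499	0.53425073
-0.174532925199	0.50459316
-0.1308996939	0.47471436
-0.0872664625997	0.44471408
-0.0436332312999	0.41469500
0	0.38476379
0.0436332312999	0.35503190
0.0872664625997	0.32561621
0.1308996939	0.29663935
0.174532925199	0.26822973
0.218166156499	0.24052119
0.261799387799	0.21365227
0.305432619099	0.18776512
0.349065850399	0.16300403
0.392699081699	0.13951367
0.436332312999	0.11743698
0.479965544298	0.09691294
0.523598775598	0.07807411
0.567232006898	0.06104422
0.610865238198	0.04593575
0.654498469498	0.03284765
0.698131700798	0.02186333
0.741764932098	0.01304888
0.785398163397	0.00645171
0.829031394697	0.00209956
0.872664625997	0.00000000
0.916297857297	0.00014039
0.959931088597	0.00248832
1.0035643199	0.00699259
1.0471975512	0.01358450
1.0908307825	0.02217970
1.1344640138	0.03268028
1.1780972451	0.04497715
1.2217304764	0.05895264
1.2653637077	0.07448313
1.308996939	0.09144164
1.3526301703	0.10970037
1.3962634016	0.12913295
1.4398966329	0.14961641
1.4835298642	0.17103275
1.5271630955	0.19327016
1.57079632679	0.21622374
1.61442955809	0.23979582
1.65806278939	0.26389588
1.70169602069	0.28844008
1.74532925199	0.31335053
1.78896248329	0.33855424
1.83259571459	0.36398196
1.87622894589	0.38956686
1.91986217719	0.41524314
1.96349540849	0.44094461
2.00712863979	0.46660332
2.05076187109	0.49214819
2.09439510239	0.51750368
2.13802833369	0.54258864
2.18166156499	0.56731508
2.22529479629	0.59158723
2.26892802759	0.61530056
2.31256125889	0.63834106
2.35619449019	0.66058467
2.39982772149	0.68189694
2.44346095279	0.70213308
2.48709418409	0.72113834
2.53072741539	0.73874897
2.57436064669	0.75479379
2.61799387799	0.76909653
2.66162710929	0.78147902
2.70526034059	0.79176533
2.74889357189	0.79978682
2.79252680319	0.80538815
2.83616003449	0.80843391
2.87979326579	0.80881574
2.92342649709	0.80645943
2.96705972839	0.80133163
3.01069295969	0.79344549
3.05432619099	0.78286484
3.09795942229	0.76970643
3.14159265359	0.75413996
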