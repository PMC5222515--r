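mw	ncic	nhdon	nhacc	rbn	hy	tpsa	mlogp
290.6024	0	0	4	8	-1.5205	155.4723	0.1649
61.6439	1	6	7	3	4.029	190.4637	-2.359
606.5239	3	1	7	2	-1.1054	15.5269	4.5573
46.8391	3	13	17	14	-2.4269	252.0838	1.4591
497.902	4	5	8	19	-2.9896	94.4787	1.4907
407.5715	0	6	3	10	-1.1118	108.9038	2.4677
150.5545	3	10	2	6	5.3952	161.6493	0.0916
624.5841	5	10	10	8	3.4487	63.8844	1.5473
198.5135	3	4	0	5	2.4679	13.9377	1.8454
360.0416	3	0	6	3	-1.2565	43.9796	-3.762
628.1266	5	0	11	5	2.3991	77.0373	2.7719
415.4917	5	0	3	5	-0.8489	64.9677	3.13
340.5507	2	6	7	2	-2.9311	61.5163	-0.2631
447.1105	2	3	5	10	1.2787	139.2423	4.5665
92.0297	4	4	2	0	-0.6172	88.4335	-5.8234
325.2115	2	6	17	5	0.9211	65.3451	4.8803
371.582	2	2	6	10	-2.07	187.2738	4.9202
622.1072	2	7	6	5	3.3321	192.4305	0.2791
281.924	2	3	5	12	0.9295	0	3.3969
236.221	1	0	9	5	1.4355	0	2.0283
259.409	2	8	10	7	1.7077	144.0372	0.1726
519.0987	2	0	0	6	1.9351	103.612	-0.6319
608.9519	2	0	0	9	-2.058	170.974	-0.2716
390.7079	2	2	4	9	-3.3458	87.7952	-2.4158
201.2932	0	4	5	7	0.1948	90.359	1.8676
0	3	0	5	8	1.5326	0	0.8424
0	6	0	5	0	-3.3679	98.3134	-2.7012
339.2588	1	5	7	13	2.0423	251.1214	1.8539
450.1544	4	4	8	0	-0.1988	215.5185	0.6577
388.1266	3	0	4	0	1.0152	0	1.6098
182.846	4	3	1	13	2.1286	5.2807	1.4606
219.7704	4	4	13	11	4.6451	19.5762	1.8882
325.5055	2	2	4	0	3.5405	28.7757	2.7144
0	2	12	6	10	-0.2643	126.3359	-0.0987
134.877	0	0	9	5	2.5414	147.8351	-1.9675
310.6015	0	1	8	15	2.5493	48.673	0.4681
336.4952	1	0	6	4	-0.0973	213.9484	4.2033
217.5417	3	1	0	2	0.5964	130.7616	4.6617
417.1262	5	1	16	7	3.1438	206.7066	1.1411
564.6902	3	5	6	16	1.3706	119.2753	3.0913
369.2211	0	2	7	0	1.8652	155.8499	-0.9312
719.8037	1	4	8	9	1.7328	0	-3.3249
320.3347	4	9	12	7	3.2713	194.3274	-0.2593
372.6464	3	4	8	18	5.4952	35.2026	-0.6536
360.9997	0	1	10	5	3.9889	99.2882	3.862
546.235	1	2	2	8	4.5621	279.98	2.7676
438.2835	2	0	4	13	1.8926	0	-2.2158
1.8093	4	11	7	6	4.3242	203.9528	4.127
0	4	2	8	2	1.7273	173.6439	1.8713
337.5476	4	0	0	15	2.2513	0	-0.1246
22.4568	3	5	3	0	4.9583	79.5719	-1.9455
586.6814	3	8	9	0	1.6366	139.7157	2.5054
451.7748	2	5	8	9	2.6158	62.4576	2.6032
134.2794	4	1	7	3	-1.391	27.2832	2.9234
68.8417	1	7	1	17	2.2667	182.3129	3.483
397.2422	3	0	0	13	0.9395	167.3277	7.9505
289.9384	0	8	6	13	4.922	19.281	-1.7123
308.5315	5	5	16	7	2.8393	116.1859	0.9103
959.1164	1	4	9	6	1.0325	205.7154	0.637
712.6848	2	4	2	8	7.7033	121.9266	0.5816
495.8411	3	7	7	5	3.7191	210.4876	4.6176
471.3614	3	7	1	15	3.635	46.198	-2.1384
326.7389	2	5	3	8	-0.0917	0	-0.0765
331.6746	5	6	3	0	5.2571	113.5407	0.6065
456.474	5	4	10	6	-6.4092	184.7572	5.0973
724.2576	3	3	11	11	1.1542	192.3316	7.1395
204.8688	2	11	4	0	-1.4973	0	4.2519
79.3501	2	0	3	0	3.2942	161.9992	-0.6995
328.4693	5	8	7	8	3.1966	0	-0.1891
417.3243	6	7	11	8	-0.4092	134.3319	2.421
454.5116	0	0	5	17	6.0701	129.3563	4.8399
435.8559	1	4	11	12	3.0537	122.281	3.9686
0	4	3	14	2	0.3845	105.6384	-0.3365
720.2389	3	2	16	3	4.6435	27.8139	-0.9205
579.4886	5	6	12	3	0.3542	181.5691	1.6717
507.5962	4	5	4	0	4.8198	250.0306	8.0411
661.5402	2	7	11	12	3.7009	208.0527	2.397
141.4456	3	8	6	15	2.855	168.411	5.062
159.3201	0	5	0	8	1.3143	193.3205	-3.6575
558.0926	0	3	5	8	1.7665	145.3367	-2.0759
74.4782	3	4	0	4	0.5181	0	0.5911
448.8015	4	0	5	11	1.2892	23.3839	-1.3134
214.3699	4	0	0	6	-0.5953	129.4094	1.3522
367.8727	4	2	17	0	-2.7323	0	0.3309
659.2871	2	5	12	6	3.7642	67.7709	-0.3633
394.8584	4	5	0	11	2.7647	188.2416	-2.3761
379.9857	1	10	12	5	4.9072	120.553	6.203
555.758	3	0	7	5	-0.4002	158.8856	-4.8969
38.7265	0	6	5	6	0.0806	113.8799	2.6665
443.3549	3	8	0	0	3.1977	0	-0.5871
41.585	4	8	3	9	-1.4673	311.9973	0.7748
671.3006	1	0	8	4	1.8384	116.3031	0.0085
107.2597	1	6	8	12	4.2356	187.4344	4.1836
209.0748	2	1	0	3	-1.8237	206.1203	-4.0271
343.0713	3	0	2	15	0.201	147.9879	-1.6453
3.1105	1	2	7	10	3.1515	0	2.712
400.8796	0	3	18	0	-0.4476	151.98	4.0121
353.5893	0	8	9	5	-2.3914	152.0457	-0.2575
321.2152	2	9	6	11	5.9095	196.7702	-2.2305
452.0739	4	0	2	7	3.9012	142.9624	0.0773
622.7682	2	5	13	9	-3.172	22.4097	-1.5406
313.1222	3	6	4	0	-3.3529	133.8777	3.4747
168.3241	3	0	16	0	2.7448	90.6103	0.9714
716.5707	2	2	6	5	-0.5455	144.6205	-0.6264
394.2778	3	5	1	0	2.8494	40.4098	-2.4827
466.6091	0	1	1	15	3.0563	227.2366	-2.959
452.5489	3	11	10	1	0.8341	122.9099	-0.6333
255.233	0	1	0	14	4.0397	154.6251	2.4349
740.8921	2	3	5	5	0.253	9.1806	3.3634
396.3477	4	3	4	4	2.7674	226.1584	3.0437
773.1865	3	3	9	6	0.5177	170.3127	-0.4554
520.7565	1	6	2	9	4.0725	0	1.8026
289.9577	3	4	15	11	-2.461	180.8656	2.9228
445.4625	1	2	3	17	6.1287	97.1643	1.2962
150.5841	4	4	17	0	0.3018	86.5144	-0.5417
128.2479	3	1	7	2	0.1534	0	1.4962
256.2301	2	7	11	7	0.9473	30.3874	0.0085
727.888	2	6	7	0	2.1048	73.1606	2.9494
127.5722	4	0	3	0	-0.4305	140.3867	5.7553
0	3	0	10	0	3.3233	314.9376	1.878
320.4239	3	7	14	8	2.6429	190.7546	2.3545
351.4305	3	7	8	1	1.8555	12.2857	-1.4544
481.2807	0	0	11	2	3.6335	0	0.9395
428.6367	5	2	2	4	0.324	113.1895	0.4843
490.5155	1	4	0	12	2.0868	176.5209	1.2468
108.6601	7	7	9	21	2.8296	0	2.6752
278.5773	5	1	0	7	-1.1733	160.2618	0.5284
307.6958	1	5	10	10	2.882	0	5.441
426.3641	1	5	11	3	-4.1836	32.6531	3.218
243.5887	6	2	10	6	0.1306	0	0.7992
547.8726	1	5	0	11	2.7832	0	2.7843
395.0725	2	6	12	9	-2.6429	53.6672	-2.7762
567.606	4	3	8	4	2.4602	0	3.0264
199.7631	2	11	19	7	-3.3503	63.3348	2.991
391.9564	1	2	9	5	-1.5799	280.2197	2.8961
173.728	3	3	5	4	1.646	110.6271	-1.0754
348.2419	4	6	8	4	0.0607	94.9534	5.707
107.5617	5	3	12	5	-0.8497	12.2893	4.0254
266.1312	0	0	10	6	-2.511	185.1655	1.2854
0	0	3	11	0	5.2384	49.7192	-0.6397
289.2063	5	5	0	11	0.9809	89.5548	2.2921
188.9593	2	0	10	7	0.2145	70.9833	2.5157
214.405	1	2	9	8	1.7181	176.8513	-1.6892
76.0176	5	5	17	6	2.5478	312.2914	1.8295
571.4204	2	0	10	10	0.4333	58.7489	-3.1041
438.9441	2	8	6	0	2.1558	40.6071	2.2643
755.7496	4	4	1	0	5.812	134.1774	-0.2425
240.36	1	3	7	6	2.1739	129.2701	1.9599
28.1126	0	5	0	2	-1.9871	43.9787	0.9376
289.0109	0	3	11	4	1.5157	88.0503	-1.4817
138.0992	4	2	9	0	1.9206	116.5132	-3.0876
468.8508	2	7	6	7	2.8236	40.4757	0.2708
368.3496	1	12	7	10	1.6199	8.3349	1.8005
0	2	3	10	1	-1.0565	133.6766	2.2813
345.4267	4	2	0	0	1.258	82.7606	-1.0043
241.3227	2	4	5	9	-0.1873	32.9099	3.0187
430.6047	4	8	13	0	2.2647	133.9676	-0.686
135.9579	3	9	4	5	2.1753	0	1.7041
419.925	2	0	12	8	1.8383	0	2.8846
577.8352	0	0	1	5	-0.5814	65.2347	0.8266
567.4398	5	1	1	12	-0.0939	0	5.0267
383.9069	2	0	4	14	-0.9221	139.8788	-1.1403
154.8584	5	1	0	0	6.2458	114.3145	5.3482
443.5552	3	0	6	1	-0.4027	131.4237	3.0646
256.9672	1	3	19	9	2.1115	20.4348	4.6791
336.9869	2	3	16	5	2.3706	0	-1.7656
497.6646	3	2	3	17	0.8737	246.19	2.1496
144.0595	4	5	6	5	0.7928	0	-0.6267
54.4641	1	4	7	6	-2.1392	3.3012	7.0728
20.8388	1	4	6	8	-0.4685	110.4658	-0.3462
545.4902	3	7	4	10	1.5486	47.4734	1.0215
0	3	7	0	8	0.2498	35.7671	2.2019
241.6002	2	5	12	9	4.748	153.8285	2.3499
360.1308	4	0	11	9	4.8916	182.6595	-1.4919
88.9891	2	3	11	2	1.127	98.2449	-1.5113
410.6537	0	8	11	0	-2.0652	126.6819	1.4179
654.6728	0	7	15	6	2.3675	1.5076	3.1111
627.126	2	4	7	9	-2.4526	115.0382	1.2589
600.4625	2	1	1	2	0.2957	149.5285	3.1254
396.7922	1	3	11	6	3.1264	102.596	-1.1839
671.4784	3	0	0	13	-0.0382	0	-3.077
199.4252	3	6	6	2	3.1203	71.4092	-2.0815
252.8186	1	0	7	3	-3.7639	114.24	2.9413
207.6778	2	1	3	1	1.5955	2.5267	1.5235
366.4146	3	2	0	15	5.0369	166.6081	-0.0151
420.142	0	0	0	0	3.7902	0.024	3.0453
421.0602	5	5	5	22	4.2849	162.8091	2.8095
573.2444	3	6	12	6	10.7915	155.2594	1.6105
621.0172	0	5	8	15	-0.1925	183.9292	0.7912
186.4994	2	2	6	1	2.8229	0	0.4725
691.6749	1	6	3	5	1.5524	0	2.8101
228.2248	5	2	10	1	4.9518	55.9847	-0.6517
539.3023	4	0	0	6	-1.4368	0	-1.5915
0	4	2	13	9	4.6431	3.0989	4.6002
457.2131	0	1	11	14	-2.5758	126.6794	1.0068
412.4373	4	0	26	11	-3.0042	55.8844	2.0954
401.6466	2	2	5	1	-4.4841	53.023	4.3254
63.1271	0	2	5	3	2.4363	4.495	4.9593
226.5314	1	0	10	15	-0.2233	89.7405	2.1622
729.3499	0	0	0	5	4.6225	243.0529	0.5301
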