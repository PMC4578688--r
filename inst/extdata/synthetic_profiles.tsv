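factor	t1	t2	t3	t4	t5	t6	t7	t8	t9	t10	t11	t12	t13	t14	t15	t16	t17	t18	t19	t20	t21	t22	t23	t24	t25
F001	0.44	0.5052	-1.3435	-0.8622	1.8412	0.2741	-0.8715	-2.8899	-1.4326	1.2721	0.5788	-1.1066	-2.0435	0.7355	0.8823	-0.1794	0.2181	0.4197	2.6999	-1.672	-0.3743	-0.6149	0.6203	0.6155	-0.6996
F002	0.9693	1.3974	0.7295	0.1624	0.6371	1.7753	0.2125	-0.3375	0.5762	0.3126	0.9762	0.0245	-0.4637	-0.5837	0.9127	-0.6154	0.6418	-0.9705	-0.6533	2.1124	0.2511	1.1399	1.0873	0.5254	-1.7846
F003	0.7611	0.6812	1.1721	0.0424	-0.2504	-0.7889	2.6779	-1.1044	-1.9908	0.6535	1.9465	0.6345	0.2558	-1.6163	-0.6208	-0.2357	0.1799	-0.1206	0.8821	-1.2334	-0.9978	-0.9736	-1.5073	1.6623	0.1808
F004	0.172	1.2102	0.9572	-0.2208	0.1091	0.9496	-0.202	1.0534	1.9446	-2.079	1.6465	0.0103	0.6808	-0.151	-0.0116	-0.1989	-0.7729	-0.6095	-0.0792	-0.4583	-1.8217	-1.2785	0.5566	0.8171	-0.7532
F005	0.4246	-1.4741	1.558	0.691	-0.1089	0.5353	0.0851	0.1666	-0.6947	-1.2088	-1.5848	0.6175	-0.1692	-1.9854	1.0123	1.4348	1.4777	0.8168	-2.1531	-0.0145	-0.8722	0.3277	-1.3338	0.8961	0.2405
F006	2.2232	0.2651	-0.6877	0.6711	-1.7779	-0.2206	1.4805	0.1912	0.0081	0.0412	0.3434	0.2502	1.0792	0.3171	-0.1458	-0.7004	0.2556	-1	-0.1473	1.177	-0.404	1.4992	0.4169	0.6071	-0.4483
F007	-0.1321	1.1118	-1.2133	0.6758	-0.4912	1.6538	-1.0775	0.1474	0.3194	-0.4108	-0.8941	1.1205	-0.5316	-0.4433	-0.9692	-0.1548	-1.3793	-0.4155	1.3651	-0.3343	0.5946	-2.3353	-0.2651	0.3556	-0.539
F008	1.16	0.0507	-0.9474	-0.775	1.9187	1.7726	1.5893	1.0713	1.1549	0.7762	-2.5411	0.1133	0.7298	0.4449	0.0882	0.2673	-0.1121	-0.4953	0.2445	1.4407	-0.7518	1.2192	-0.9064	0.7541	-1.7658
F009	0.3494	-0.5438	1.048	1.5094	0.0421	0.3729	0.7515	0.3912	1.4453	0.4665	-1.4078	0.356	1.0735	0.1957	0.1268	1.0494	0.387	2.0107	-0.4734	-1.9612	1.4659	-0.654	0.9958	-1.1229	-1.5394
F010	-0.3883	0.2037	0.6457	0.4986	-0.6567	0.2611	2.5526	0.6689	-1.5737	1.2571	-3.0389	-0.7597	0.8684	0.2832	0.971	-0.1894	-0.0145	1.1806	0.5519	0.862	1.1641	-1.5691	-0.3228	-0.4755	0.3928
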