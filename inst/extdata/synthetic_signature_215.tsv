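gene_id	weight
SYNG0464	1
SYNG1511	1
SYNG0661	1
SYNG3561	1
SYNG2488	1
SYNG3894	1
SYNG4552	1
SYNG2548	1
SYNG1909	1
SYNG1289	1
SYNG3804	1
SYNG2756	1
SYNG4712	1
SYNG0678	1
SYNG4854	1
SYNG1857	1
SYNG4282	1
SYNG1442	1
SYNG0268	1
SYNG2581	1
SYNG0491	1
SYNG1870	1
SYNG0372	1
SYNG4009	1
SYNG0369	1
SYNG2803	1
SYNG3379	1
SYNG4375	1
SYNG3677	1
SYNG1482	1
SYNG3906	1
SYNG4239	1
SYNG3739	1
SYNG3618	1
SYNG4654	1
SYNG0486	1
SYNG3271	1
SYNG1755	1
SYNG1003	1
SYNG0166	1
SYNG4160	1
SYNG2958	1
SYNG4137	1
SYNG0781	1
SYNG0045	1
SYNG1896	1
SYNG0731	1
SYNG1359	1
SYNG1409	1
SYNG0989	1
SYNG4859	1
SYNG1166	1
SYNG2567	1
SYNG1919	1
SYNG1100	1
SYNG4683	1
SYNG4109	1
SYNG2608	1
SYNG3314	1
SYNG1398	1
SYNG0816	1
SYNG2696	1
SYNG1899	1
SYNG1139	1
SYNG2461	1
SYNG1713	1
SYNG2876	1
SYNG3477	1
SYNG4610	1
SYNG3080	1
SYNG0227	1
SYNG3429	1
SYNG3852	1
SYNG4947	1
SYNG0003	1
SYNG1566	1
SYNG0134	1
SYNG0473	1
SYNG2994	1
SYNG0909	1
SYNG0751	1
SYNG3064	1
SYNG2547	1
SYNG0273	1
SYNG1225	1
SYNG4005	1
SYNG3501	1
SYNG0624	1
SYNG0033	1
SYNG4855	1
SYNG4408	1
SYNG4176	1
SYNG2706	1
SYNG2157	1
SYNG1212	1
SYNG4614	1
SYNG3710	1
SYNG4100	1
SYNG0447	1
SYNG3950	1
SYNG2294	1
SYNG1378	1
SYNG1697	1
SYNG4825	1
SYNG3420	1
SYNG0920	1
SYNG1880	1
SYNG2252	1
SYNG2560	1
SYNG4881	1
SYNG3096	1
SYNG2374	1
SYNG4004	1
SYNG1955	1
SYNG0378	1
SYNG1631	1
SYNG0849	1
SYNG0812	1
SYNG2168	1
SYNG4381	1
SYNG4692	1
SYNG0763	1
SYNG2226	-1
SYNG2532	-1
SYNG2058	-1
SYNG0182	-1
SYNG0692	-1
SYNG4139	-1
SYNG1756	-1
SYNG4715	-1
SYNG4428	-1
SYNG2673	-1
SYNG3446	-1
SYNG1052	-1
SYNG3808	-1
SYNG4002	-1
SYNG1533	-1
SYNG2523	-1
SYNG4645	-1
SYNG2114	-1
SYNG4061	-1
SYNG4699	-1
SYNG0497	-1
SYNG4387	-1
SYNG4869	-1
SYNG3072	-1
SYNG1305	-1
SYNG0157	-1
SYNG0120	-1
SYNG2730	-1
SYNG3133	-1
SYNG0674	-1
SYNG2052	-1
SYNG4388	-1
SYNG1846	-1
SYNG0039	-1
SYNG0978	-1
SYNG4696	-1
SYNG1221	-1
SYNG3530	-1
SYNG0188	-1
SYNG2787	-1
SYNG1265	-1
SYNG4170	-1
SYNG4057	-1
SYNG4638	-1
SYNG0757	-1
SYNG0167	-1
SYNG4544	-1
SYNG3857	-1
SYNG0543	-1
SYNG3406	-1
SYNG1433	-1
SYNG1108	-1
SYNG4208	-1
SYNG0143	-1
SYNG3625	-1
SYNG4320	-1
SYNG2851	-1
SYNG0256	-1
SYNG2326	-1
SYNG0117	-1
SYNG3595	-1
SYNG1410	-1
SYNG3974	-1
SYNG2459	-1
SYNG4467	-1
SYNG1887	-1
SYNG3333	-1
SYNG1383	-1
SYNG2574	-1
SYNG2589	-1
SYNG2314	-1
SYNG4901	-1
SYNG3738	-1
SYNG4382	-1
SYNG0228	-1
SYNG2418	-1
SYNG0732	-1
SYNG0423	-1
SYNG2474	-1
SYNG4150	-1
SYNG3827	-1
SYNG0714	-1
SYNG1168	-1
SYNG0127	-1
SYNG2359	-1
SYNG1366	-1
SYNG3754	-1
SYNG2915	-1
SYNG1401	-1
SYNG2311	-1
SYNG0190	-1
SYNG1085	-1
SYNG2653	-1
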