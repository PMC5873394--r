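model	akinete_ga	node	median_ma	hpd_lower_ma	hpd_upper_ma
A	1.2	Root age	3591	3323	3837
A	1.2	Stem Cyanobacteria	2825	2570	3195
A	1.2	Crown Cyanobacteria	2305	2026	2601
A	1.2	Crown Cyanobacteria excl Gloeobacter	1943	1723	2188
A	1.2	Stem GNS	2099	1584	2674
A	1.2	Crown GNS	1041	624	1542
A	1.2	Stem GSB	2640	2298	2977
A	1.2	Crown GSB	1798	1641	2112
D	1.2	Root age	3624	3483	3884
D	1.2	Stem Cyanobacteria	2776	2396	2934
D	1.2	Crown Cyanobacteria	2244	1912	2419
D	1.2	Crown Cyanobacteria excl Gloeobacter	1902	1713	2096
D	1.2	Stem GNS	2861	2498	3004
D	1.2	Crown GNS	1986	1682	2433
D	1.2	Stem GSB	2561	2263	2853
D	1.2	Crown GSB	1716	1645	1950
A	1.6	Root age	3692	3408	3968
A	1.6	Stem Cyanobacteria	3158	2886	3486
A	1.6	Crown Cyanobacteria	2677	2426	2972
A	1.6	Crown Cyanobacteria excl Gloeobacter	2328	2098	2564
A	1.6	Stem GNS	2253	1597	2785
A	1.6	Crown GNS	1111	618	1714
A	1.6	Stem GSB	2602	2265	2981
A	1.6	Crown GSB	1793	1640	2112
D	1.6	Root age	3692	3569	3920
D	1.6	Stem Cyanobacteria	2836	2724	2936
D	1.6	Crown Cyanobacteria	2515	2382	2593
D	1.6	Crown Cyanobacteria excl Gloeobacter	2234	2087	2360
D	1.6	Stem GNS	2922	2759	2950
D	1.6	Crown GNS	2109	1810	2438
D	1.6	Stem GSB	2737	2423	2902
D	1.6	Crown GSB	1719	1660	2173
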