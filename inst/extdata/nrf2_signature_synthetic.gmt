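# synthetic stand-ins shaped like the published NRF2/RELA signatures (sizes 68+75 and 304+85)
NRF2_UP_SYNTHETIC	up	G00188	G00347	G00374	G00387	G00451	G00505	G00704	G00846	G01074	G01103	G01167	G01211	G01304	G01314	G01352	G01439	G01566	G01575	G01667	G01773	G01807	G01808	G01848	G01871	G01952	G02069	G02136	G02148	G02193	G02505	G02519	G02694	G02717	G02746	G02780	G02808	G02868	G02872	G02921	G03013	G03306	G03352	G03382	G03447	G03603	G03613	G03644	G03698	G03703	G03711	G03768	G03794	G03831	G03872	G03901	G03955	G04128	G04148	G04270	G04389	G04582	G04622	G04709	G04713	G04754	G04794	G04840	G04916
NRF2_DOWN_SYNTHETIC	down	G00020	G00143	G00148	G00389	G00420	G00458	G00471	G00825	G00888	G00901	G00988	G01157	G01212	G01278	G01404	G01433	G01502	G01659	G01664	G01825	G01872	G01978	G01980	G02002	G02082	G02088	G02103	G02146	G02155	G02231	G02256	G02443	G02529	G02588	G02673	G02793	G02799	G02838	G02850	G02881	G02911	G02942	G02944	G02982	G03093	G03130	G03222	G03375	G03506	G03512	G03563	G03594	G03666	G03684	G03752	G03848	G03932	G03987	G04103	G04129	G04187	G04281	G04381	G04415	G04491	G04497	G04523	G04641	G04705	G04864	G04880	G04886	G04892	G04919	G04920
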