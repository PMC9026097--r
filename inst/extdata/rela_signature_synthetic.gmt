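# synthetic stand-ins shaped like the published NRF2/RELA signatures (sizes 68+75 and 304+85)
RELA_ACTIVATED_SYNTHETIC	activated	G00054	G00108	G00111	G00142	G00152	G00174	G00186	G00235	G00242	G00279	G00293	G00307	G00314	G00411	G00431	G00465	G00472	G00481	G00490	G00528	G00531	G00532	G00534	G00553	G00565	G00566	G00576	G00586	G00609	G00645	G00656	G00699	G00705	G00708	G00709	G00716	G00724	G00738	G00739	G00775	G00803	G00816	G00830	G00861	G00885	G00896	G00902	G00917	G00923	G00969	G00979	G01010	G01024	G01072	G01085	G01119	G01129	G01134	G01149	G01168	G01176	G01200	G01215	G01231	G01251	G01277	G01281	G01286	G01359	G01396	G01407	G01414	G01426	G01451	G01461	G01467	G01493	G01524	G01540	G01551	G01554	G01564	G01573	G01574	G01578	G01599	G01622	G01641	G01643	G01663	G01677	G01682	G01712	G01724	G01751	G01755	G01775	G01782	G01795	G01796	G01801	G01823	G01838	G01865	G01882	G01897	G01924	G01925	G01940	G01943	G01944	G01959	G01975	G01985	G02000	G02032	G02043	G02054	G02097	G02106	G02111	G02125	G02131	G02184	G02185	G02200	G02207	G02216	G02218	G02219	G02239	G02296	G02307	G02323	G02328	G02340	G02344	G02357	G02389	G02416	G02420	G02430	G02490	G02504	G02514	G02515	G02548	G02567	G02591	G02615	G02631	G02635	G02641	G02668	G02698	G02714	G02732	G02742	G02759	G02771	G02772	G02783	G02787	G02817	G02859	G02870	G02891	G02899	G02922	G03004	G03011	G03019	G03033	G03046	G03051	G03066	G03084	G03111	G03126	G03156	G03169	G03175	G03207	G03221	G03226	G03227	G03238	G03268	G03269	G03299	G03314	G03323	G03341	G03343	G03396	G03417	G03434	G03445	G03456	G03457	G03463	G03469	G03470	G03487	G03492	G03493	G03509	G03523	G03534	G03536	G03545	G03591	G03597	G03611	G03614	G03626	G03629	G03630	G03647	G03691	G03707	G03709	G03758	G03781	G03796	G03818	G03829	G03862	G03873	G03877	G03878	G03879	G03887	G03889	G03927	G03957	G03969	G03992	G03997	G04004	G04014	G04079	G04106	G04117	G04126	G04147	G04167	G04172	G04181	G04203	G04208	G04211	G04219	G04221	G04222	G04225	G04249	G04267	G04273	G04319	G04321	G04333	G04359	G04371	G04374	G04380	G04422	G04428	G04435	G04451	G04460	G04493	G04503	G04551	G04571	G04575	G04602	G04607	G04621	G04633	G04638	G04666	G04679	G04702	G04714	G04729	G04735	G04753	G04761	G04773	G04780	G04783	G04817	G04819	G04829	G04859	G04887	G04903	G04918	G04927	G04954	G04960	G04980	G04990
RELA_SUPPRESSED_SYNTHETIC	suppressed	G00103	G00107	G00126	G00286	G00295	G00302	G00424	G00463	G00496	G00555	G00567	G00688	G00762	G00906	G00982	G00998	G01014	G01034	G01130	G01136	G01191	G01202	G01219	G01438	G01542	G01565	G01630	G01706	G01710	G01738	G01832	G01917	G01950	G01981	G02045	G02077	G02265	G02271	G02284	G02286	G02348	G02444	G02475	G02496	G02528	G02612	G02650	G02701	G02728	G02776	G02831	G02864	G02904	G03105	G03223	G03230	G03270	G03290	G03332	G03393	G03404	G03441	G03485	G03498	G03565	G03577	G03667	G03845	G03857	G03881	G04197	G04239	G04251	G04304	G04308	G04419	G04425	G04462	G04499	G04608	G04643	G04931	G04933	G04945	G04983
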