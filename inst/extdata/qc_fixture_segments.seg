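sample	chrom	start	end	seg.mean
S01	chr1	1087	1187	0.15
S01	chr1	1224	1324	0.6
S01	chr1	1498	1598	0
S01	chr1	1635	1735	0
S01	chr1	1772	1872	-0.15
S01	chr1	1909	2009	0
S01	chr1	2046	2146	-0.7
S01	chr1	2183	2283	0
S01	chr1	2320	2420	0
S02	chr1	2457	2557	0.15
S02	chr1	2594	2694	0.6
S02	chr1	2868	2968	0
S02	chr1	3005	3105	0
S02	chr1	3142	3242	-0.15
S02	chr1	3279	3379	0
S02	chr1	3416	3516	-0.7
S02	chr1	3553	3653	0
S02	chr1	3690	3790	0
S03	chr1	3827	3927	0.15
S03	chr1	3964	4064	0.6
S03	chr1	4238	4338	0
S03	chr1	4375	4475	0
S03	chr1	4512	4612	-0.15
S03	chr1	4649	4749	0
S03	chr1	4786	4886	-0.7
S03	chr1	4923	5023	0
S03	chr1	5060	5160	0
S04	chr1	5197	5297	0.15
S04	chr1	5334	5434	0.6
S04	chr1	5608	5708	0
S04	chr1	5745	5845	0
S04	chr1	5882	5982	-0.15
S04	chr1	6019	6119	0
S04	chr1	6156	6256	-0.7
S04	chr1	6293	6393	0
S04	chr1	6430	6530	0
S05	chr1	6567	6667	0.15
S05	chr1	6704	6804	0.6
S05	chr1	6978	7078	0
S05	chr1	7115	7215	0
S05	chr1	7252	7352	-0.15
S05	chr1	7389	7489	0
S05	chr1	7526	7626	-0.7
S05	chr1	7663	7763	0
S05	chr1	7800	7900	0
S06	chr1	7937	8037	0.15
S06	chr1	8074	8174	0.6
S06	chr1	8348	8448	0
S06	chr1	8485	8585	0
S06	chr1	8622	8722	-0.15
S06	chr1	8759	8859	0
S06	chr1	8896	8996	-0.7
S06	chr1	9033	9133	0
S06	chr1	9170	9270	0
S07	chr1	9307	9407	0.15
S07	chr1	9444	9544	0.6
S07	chr1	9718	9818	0
S07	chr1	9855	9955	0
S07	chr1	9992	10092	-0.15
S07	chr1	10129	10229	0
S07	chr1	10266	10366	-0.7
S07	chr1	10403	10503	0
S07	chr1	10540	10640	0
S08	chr1	10677	10777	0.15
S08	chr1	10814	10914	0.6
S08	chr1	11088	11188	0
S08	chr1	11225	11325	0
S08	chr1	11362	11462	-0.15
S08	chr1	11499	11599	0
S08	chr1	11636	11736	-0.7
S08	chr1	11773	11873	0
S08	chr1	11910	12010	0
S09	chr1	12047	12147	0.15
S09	chr1	12184	12284	0.6
S09	chr1	12458	12558	0
S09	chr1	12595	12695	0
S09	chr1	12732	12832	-0.15
S09	chr1	12869	12969	0
S09	chr1	13006	13106	-0.7
S09	chr1	13143	13243	0
S09	chr1	13280	13380	0
S10	chr1	13417	13517	0.15
S10	chr1	13554	13654	0.6
S10	chr1	13828	13928	0
S10	chr1	13965	14065	0
S10	chr1	14102	14202	-0.15
S10	chr1	14239	14339	0
S10	chr1	14376	14476	-0.7
S10	chr1	14513	14613	0
S10	chr1	14650	14750	0
S11	chr1	14787	14887	0.15
S11	chr1	14924	15024	0.6
S11	chr1	15198	15298	0
S11	chr1	15335	15435	0
S11	chr1	15472	15572	-0.15
S11	chr1	15609	15709	0
S11	chr1	15746	15846	-0.7
S11	chr1	15883	15983	0
S11	chr1	16020	16120	0
S12	chr1	16157	16257	0.15
S12	chr1	16294	16394	0.6
S12	chr1	16568	16668	0
S12	chr1	16705	16805	0
S12	chr1	16842	16942	-0.15
S12	chr1	16979	17079	0
S12	chr1	17116	17216	-0.7
S12	chr1	17253	17353	0
S12	chr1	17390	17490	0
S13	chr1	17527	17627	0.15
S13	chr1	17664	17764	0.6
S13	chr1	17938	18038	0
S13	chr1	18075	18175	0
S13	chr1	18212	18312	-0.15
S13	chr1	18349	18449	0
S13	chr1	18486	18586	-0.7
S13	chr1	18623	18723	0
S13	chr1	18760	18860	0
S14	chr1	18897	18997	0.15
S14	chr1	19034	19134	0.6
S14	chr1	19308	19408	0
S14	chr1	19445	19545	0
S14	chr1	19582	19682	-0.15
S14	chr1	19719	19819	0
S14	chr1	19856	19956	-0.7
S14	chr1	19993	20093	0
S14	chr1	20130	20230	0
S15	chr1	20267	20367	0.15
S15	chr1	20404	20504	0.6
S15	chr1	20678	20778	0
S15	chr1	20815	20915	0
S15	chr1	20952	21052	-0.15
S15	chr1	21089	21189	0
S15	chr1	21226	21326	-0.7
S15	chr1	21363	21463	0
S15	chr1	21500	21600	0
S16	chr1	21637	21737	0.15
S16	chr1	21774	21874	0.6
S16	chr1	22048	22148	0
S16	chr1	22185	22285	0
S16	chr1	22322	22422	-0.15
S16	chr1	22459	22559	0
S16	chr1	22596	22696	-0.7
S16	chr1	22733	22833	0
S16	chr1	22870	22970	0
S17	chr1	23007	23107	0.15
S17	chr1	23144	23244	0.6
S17	chr1	23418	23518	0
S17	chr1	23555	23655	0
S17	chr1	23692	23792	-0.15
S17	chr1	23829	23929	0
S17	chr1	23966	24066	-0.7
S17	chr1	24103	24203	0
S17	chr1	24240	24340	0
S18	chr1	24377	24477	0.15
S18	chr1	24514	24614	0.6
S18	chr1	24788	24888	0
S18	chr1	24925	25025	0
S18	chr1	25062	25162	-0.15
S18	chr1	25199	25299	0
S18	chr1	25336	25436	-0.7
S18	chr1	25473	25573	0
S18	chr1	25610	25710	0
S19	chr1	25747	25847	0
S19	chr1	25884	25984	0
S19	chr1	26021	26121	0
S19	chr1	26158	26258	0
S19	chr1	26295	26395	0
S19	chr1	26432	26532	0
S19	chr1	26569	26669	0
S19	chr1	26706	26806	0
S19	chr1	26843	26943	0
S19	chr1	26980	27080	0
S19	chr1	27117	27217	0
S19	chr1	27254	27354	0
S19	chr1	27391	27491	0
S19	chr1	27528	27628	0
S19	chr1	27665	27765	0
S20	chr1	27802	27902	0
S20	chr1	27939	28039	0
S20	chr1	28076	28176	0
S20	chr1	28213	28313	0
S20	chr1	28350	28450	0
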