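synthetic_pathway_01	synthetic gene set for demonstration	g00451	g01808	g01871	g02519	g03447	g03644	g03698	g03955	g04709	g05166	g05197	g05973	g06189	g06321	g07228	g07549	g08380	g08566	g09038	g09266	g09359	g09403	g09544	g09758	g09767
synthetic_pathway_02	synthetic gene set for demonstration	g00347	g01304	g01773	g02193	g02780	g02868	g03703	g03768	g03794	g03901	g04148	g04713	g04754	g05173	g05182	g05285	g05396	g05421	g06100	g06110	g06959	g08191	g08579	g08896	g09506
synthetic_pathway_03	synthetic gene set for demonstration	g00505	g01667	g01848	g01952	g02148	g02505	g02793	g02808	g02921	g03013	g03130	g03613	g03872	g03932	g04187	g04415	g04497	g05595	g05688	g05869	g07035	g08335	g09295	g09631	g09851
synthetic_pathway_04	synthetic gene set for demonstration	g00020	g00420	g00458	g00471	g00988	g01212	g01433	g01825	g02103	g02529	g02942	g03512	g03684	g03752	g03987	g04381	g04880	g05172	g05730	g05898	g06486	g09080	g09180	g09596	g09694
synthetic_pathway_05	synthetic gene set for demonstration	g00901	g01157	g01664	g01872	g02082	g02088	g02256	g02799	g02838	g03222	g03506	g03563	g03594	g04281	g05251	g06083	g06839	g07285	g07325	g08081	g08340	g08581	g09017	g09093	g09470
synthetic_pathway_06	synthetic gene set for demonstration	g00490	g00775	g01286	g01712	g02184	g02668	g02799	g03493	g03829	g03873	g05690	g06403	g06484	g06669	g06827	g07184	g07785	g07947	g08366	g08623	g08995	g09423	g09606	g09770	g09874
synthetic_pathway_07	synthetic gene set for demonstration	g00108	g00186	g00472	g00739	g01281	g01865	g02000	g02054	g02296	g03051	g03445	g04319	g04380	g04451	g04621	g04904	g04982	g05267	g05487	g06286	g08380	g08726	g09321	g09716	g09835
synthetic_pathway_08	synthetic gene set for demonstration	g00576	g00816	g00979	g01796	g01823	g02200	g02296	g02771	g03269	g04004	g04208	g04435	g05379	g05657	g05662	g06006	g07392	g07452	g07859	g08052	g08344	g08427	g08657	g09341	g09732
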