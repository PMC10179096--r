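subgroup	reference	ortholog	annotation
IV-I	Gh_A03G0826	Gbar_A03G010660	GPI-anchored adhesin-like protein
IV-I	Gh_A07G1193	Gbar_A07G013810	S-adenosylmethionine synthase
IV-I	Gh_A11G1313	Gbar_A11G014750	Stomagen
IV-I	Gh_A11G3137	Gbar_A11G021290	3-hydroxyacyl-CoA dehydratase
IV-I	Gh_A13G0932	Gbar_A13G012640	SMALLER WITH VARIABLE BRANCHES
IV-I	Gh_D03G0078	Gbar_D03G000870	alpha-mannosidase
IV-I	Gh_D05G3507	Gbar_D05G037750	(+)-delta-cadinene synthase
IV-I	Gh_D08G1067	Gbar_D08G011240	BAHD acyltransferase
IV-I	Gh_D09G0438	Gbar_D09G004860	Subtilisin-like protease
IV-I	Gh_D11G1462	Gbar_D11G015570	Stomagen
IV-II	Gh_A03G2157	Gbar_A03G019080	Nonspecific lipid-transfer protein
IV-II	Gh_A05G1646	Gbar_A05G018970	beta-mannanase
IV-II	Gh_A05G1812	Gbar_A05G020690	TWISTED SEED
IV-II	Gh_A07G0152	Gbar_A07G001880	Pectinesterase/pectinesterase inhibitor
IV-II	Gh_A07G0664	Gbar_A07G007890	alpha-expansin
IV-II	Gh_A08G0668	Gbar_A08G007900	BTB/POZ domain-containing protein
IV-II	Gh_A09G1368	Gbar_A09G015680	S-adenosylmethionine synthase
IV-II	Gh_A11G0547	Gbar_A11G006130	Serine protease inhibitor
IV-II	Gh_A12G1104	Gbar_A12G013240	Ribonuclease H-like protein
IV-II	Gh_D04G0006	Gbar_D04G000050	Pectinesterase/pectinesterase inhibitor
IV-II	Gh_D05G2968	Gbar_D05G031740	Importin-beta
IV-II	Gh_D07G1581	Gbar_D07G017340	Acidic leucine-rich nuclear phosphoprotein
IV-II	Gh_D08G0151	Gbar_D08G001620	Dirigent protein
IV-II	Gh_D09G1136	Gbar_D09G012750	Alpha carbonic anhydrase
IV-II	Gh_D10G1363	Gbar_D10G014320	Methylenetetrahydrofolate reductase
IV-II	Gh_D11G0625	Gbar_D11G006420	Fatty acid amide hydrolase
IV-II	Gh_D11G3426	Gbar_D11G024050	Glutathione S-transferase
IV-II	Gh_D12G2436	Gbar_D12G026630	Heat shock protein
IV-III	Gh_A02G1644	Gbar_A02G018320	alpha-mannosidase
IV-III	Gh_A05G0923	Gbar_A05G010310	Heavy metal transport
IV-III	Gh_A05G3172	Gbar_A05G037170	ANTIAUXIN-RESISTANT
IV-III	Gh_A06G1116	Gbar_A06G013440	Cystathionine beta-synthase
IV-III	Gh_A07G2014	Gbar_A07G023310	Formate dehydrogenase
IV-III	Gh_A10G0126	Gbar_A10G001450	Actin cytoskeleton-regulatory complex
IV-III	Gh_D04G0153	Gbar_D04G001950	Cytochrome P450
IV-III	Gh_D04G1621	Gbar_D04G017890	Cytosolic cyclophilin
IV-III	Gh_D05G2178	Gbar_D05G023090	Sugar transport protein
IV-III	Gh_D08G2441	Gbar_D08G025770	Leucine-rich repeat (LRR) protein
IV-III	Gh_D09G1484	Gbar_D09G016550	Short-chain dehydrogenase
IV-III	Gh_D11G1941	Gbar_D11G020770	PLC-like phosphodiesterase
IV-III	Gh_D12G0289	Gbar_D12G003220	SAUR-like auxin-responsive protein
IV-III	Gh_D12G0652	Gbar_D12G007360	Membrane-associated kinase regulator
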