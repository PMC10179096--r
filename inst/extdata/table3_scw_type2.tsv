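reference	ortholog	annotation	marker
Gh_A03G1620	Gbar_A03G020290	Progesterone 5beta-reductase	HEBAU0022
Gh_A05G0912	Gbar_A05G010210	BEL1-like homeodomain protein	HEBAU0023
Gh_A05G1599	Gbar_A05G018470	Endo-beta-1, 4-glucanase	HEBAU0024
Gh_A06G0882	Gbar_A06G010210	Transmembrane protein	HEBAU0025
Gh_A06G1256	Gbar_A06G015550	Aldehyde dehydrogenase	HEBAU0026
Gh_A07G0322	Gbar_A07G004070	Cellulose synthase	NA
Gh_A09G0389	NA	Protein of unknown function	NA
Gh_A10G0145	Gbar_A10G001660	NTF2-like protein	NA
Gh_A10G0696	Gbar_A10G008340	ABC transporter	HEBAU0027
Gh_A12G0108	Gbar_A12G001190	Protein of unknown function	HEBAU0028
Gh_A12G1564	Gbar_A12G018330	SLH domain protein	HEBAU0029
Gh_A12G2552	Gbar_A12G010170	Hydroxyproline-rich glycoprotein	HEBAU0030
Gh_A13G0149	Gbar_A13G001740	Auxin influx transporter	HEBAU0031
Gh_A13G0378	Gbar_A13G004310	Leucine-rich repeat (LRR) protein	HEBAU0032
Gh_A13G1904	Gbar_A13G023450	Epoxide hydrolase	HEBAU0033
Gh_A13G2039	Gbar_A13G024860	Networked (NET) family protein	HEBAU0034
Gh_A13G2237	NA	Protein of unknown function	NA
Gh_D03G0611	Gbar_D03G007510	Cellulose synthase	HEBAU0035
Gh_D05G2536	Gbar_D05G026930	Blue copper protein	HEBAU0036
Gh_D06G1911	Gbar_D06G019950	RING-type E3 ubiquitin ligase	HEBAU0037
Gh_D08G1431	Gbar_D08G015060	Subtilisin-like protease	HEBAU0038
Gh_D10G1810	Gbar_D10G018890	UDP-glycosyltransferase	NA
Gh_D12G0575	Gbar_D12G006270	Kinesin-like protein	HEBAU0039
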