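reference	ortholog	annotation	marker
Gh_A04G0686	Gbar_A04G008430	Soluble inorganic pyrophosphatase	HEBAU0001
Gh_A05G0370	Gbar_A05G004360	F-box/LRR-repeat protein	HEBAU0002
Gh_A05G1677	Gbar_A05G019310	C2H2-like zinc finger protein	HEBAU0003
Gh_A05G1930	Gbar_A05G022250	EXORDIUM protein	NA
Gh_A05G2177	Gbar_A05G025000	Transmembrane protein	HEBAU0004
Gh_A06G1590	Gbar_A06G019480	Leucine-rich repeat protein kinase	HEBAU0005
Gh_A10G1937	Gbar_A10G023160	UDP-Xyl synthase	HEBAU0006
Gh_A11G2936	Gbar_A11G034900	Laccase	HEBAU0007
Gh_A12G0165	Gbar_A12G001790	Nucleobase-ascorbate transporter	HEBAU0008
Gh_A13G0090	GB_A13G0103	Cysteine/histidine-rich DC1 domain	HEBAU0009
Gh_A13G1919	Gbar_A13G023580	Fasciclin-like arabinogalactan protein	HEBAU0010
Gh_D01G1187	Gbar_D01G013340	Protein of unknown function	HEBAU0011
Gh_D02G0286	GB_D02G0284	Cytochrome P450	HEBAU0012
Gh_D02G1423	Gbar_D02G015210	Plasmodesmata-located protein	NA
Gh_D03G0537	Gbar_D03G005540	Cytochrome P450	HEBAU0013
Gh_D03G1074	Gbar_D03G011820	Feruloyl-CoA transferase	HEBAU0014
Gh_D04G1519	Gbar_D04G016960	2-nitropropane dioxygenase	HEBAU0015
Gh_D05G1062	Gbar_D05G011330	LIGHT SENSITIVE HYPOCOTYLS	HEBAU0016
Gh_D05G2936	Gbar_D05G031310	Phosphate transporter	HEBAU0017
Gh_D06G2276	Gbar_D06G000230	beta-tubulin	HEBAU0018
Gh_D07G0285	Gbar_D07G003310	Clathrin assembly protein	NA
Gh_D09G0011	Gbar_D09G000120	Protein of unknown function	HEBAU0019
Gh_D10G1036	Gbar_D10G011020	Xylan glucuronosyltransferase	HEBAU0020
Gh_D10G1767	Gbar_D10G018450	beta-xylosidase	HEBAU0021
Gh_D12G2377	Gbar_D12G025300	Protein of unknown function	NA
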