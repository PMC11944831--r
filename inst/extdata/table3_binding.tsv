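name	formula	mz	rt_min	ion_mode	adduct
Epiberberine	C20H17NO4	336.12263	12.735	positive	[M+H]+
Palmatine	C21H21NO4	352.15407	12.696	positive	[M+H]+
Jatrorrhizine	C20H19NO4	338.13866	11.872	positive	[M+H]+
(+)-Magnoflorine	C20H23NO4	342.16997	8.584	positive	[M+H]+
Berberrubine	C19H15NO4	322.10752	10.559	positive	[M+H]+
Demethyleneberberine	C19H17NO4	324.12316	10.732	positive	[M+H]+
Nobiletin	C21H22O8	403.13876	15.267	positive	[M+H]+
Sinensetin	C20H20O7	373.12831	14.714	positive	[M+H]+
Formononetin	C16H12O4	269.08093	14.401	positive	[M+H]+
Dehydroglaucine	C21H23NO4	354.16999	11.123	positive	[M+H]+
6-Demethoxytangeretin	C19H18O6	343.11792	15.312	positive	[M+H]+
Quinic acid	C7H12O6	191.05673	1.02	negative	[M-H]-
Oroxylin A-7-O-b-d-glucuronide	C22H20O11	459.09442	13.101	negative	[M-H]-
TF-Hesperidin	C28H34O15	609.184	11.383	negative	[M-H]-
Narirutin	C27H32O14	579.17336	10.778	negative	[M-H]-
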