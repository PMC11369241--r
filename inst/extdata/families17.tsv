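family	allele	cdna	protein	acmg	zygosity	detected_by	region
F1	1,2	c.15037_15048delinsGATGATATA	p.(Tyr5013_Pro5016delinsAspAspIle)	LP	hom	SR	unique
F2	1,2	c.15037_15048delinsGATGATATA	p.(Tyr5013_Pro5016delinsAspAspIle)	LP	hom	SR	unique
F3	1	c.8487_8489delinsCA	p.(Pro2830Hisfs*23)	LP	het	SR	homology
F3	2	c.1529del	p.(Phe510Serfs*43)	P	het	SR	homology
F4	1	c.1529del	p.(Phe510Serfs*43)	P	het	SR	homology
F4	2	c.6669+1G>A	p.?	LP	het	SR	homology
F5	1	c.1949G>A	p.(Arg650His)	VUS	het	SR	homology
F5	2	c.3640A>G	p.(Ile1214Val)	VUS	het	SR	homology
F6	1	c.10886_10902del	p.(Asp3629ValfsTer9)	LP	het	SR	homology
F6	2	c.14157T>G	p.(Tyr4719Ter)	LP	het	SR	homology
F7	1	c.3252dup	p.(Val1085ArgfsTer15)	P	het	SR	homology
F7	2	c.1670G>C	p.(Arg557Thr)	LP	het	SR	homology
F8	1,2	c.12444-1G>A	p.?	LP	hom	SR	homology
F9	1,2	c.10012G>T	p.(Glu338Ter)	P	hom	SR	homology
F10	1	c.283C>T	p.(Gln95Ter)	LP	het	SR	unique
F10	2	c.13680-3A>G	p.?	VUS	het	SR	homology
F11	1	c.2419_2422del	p.(Val807IlefsTer13)	LP	het	SR	homology
F11	2	c.5620-311_5788+1198del	p.?	LP	het	LR	homology
F12	1	c.6669+1G>A	p.?	LP	het	SR	homology
F12	2	c.5789-39A>G	p.?	VUS	het	SR	homology
F13	1	c.1095del	p.(Phe365LeufsTer64)	LP	het	SR	homology
F13	2	c.2376+752_2529+9004del	p.?	LP	het	LR	homology
F14	1	c.1147C>T	p.(Arg383Ter)	P	het	SR	homology
F14	2	c.4888A>T	p.(Lys1630Ter)	P	het	SR	homology
F15	1	c.12144dup	p.(Thr4049HisfsTer9)	LP	het	SR	homology
F15	2	c.2702G>T	p.(Gly901Val)	VUS	het	SR	homology
F16	1,2	c.7214_7215del	p.(Ser2405CysfsTer2)	LP	hom	SR	homology
F17	1,2	c.13709del	p.(Pro4570LeufsTer22)	P	hom	SR	homology
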