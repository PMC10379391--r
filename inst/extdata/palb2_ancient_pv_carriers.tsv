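carrier_number	cdna	protein	mutation_type	domain	arisen_time_bp
4	c.3256C>T	p.Arg1086Ter	stopgain	WD40	9860
3	c.2257C>T	p.Arg753Ter	stopgain	-	3325
3	c.2509G>A	p.Glu837Lys	nonsynonymous SNV	-	7050
3	c.2834+1G>A	-	splice site	WD40	6319
2	c.212-1G>A	-	splice site	ETGE	2275
2	c.211+1G>A	-	splice site	ETGE	10050
2	c.1042C>T	p.Gln348Ter	stopgain	-	6319
2	c.1117G>T	p.Glu373Ter	stopgain	-	3157
2	c.1240C>T	p.Arg414Ter	stopgain	ChAM	3740
2	c.1837C>T	p.Gln613Ter	stopgain	-	32895
2	c.2218C>T	p.Gln740Ter	stopgain	-	8315
2	c.2512C>T	p.Gln838Ter	stopgain	-	3871
2	c.2515-1G>A	-	splice site	-	4106
2	c.2630G>A	p.Trp877Ter	stopgain	WD40	5677
2	c.2693G>A	p.Trp898Ter	stopgain	WD40	>10000
2	c.3523C>T	p.Gln1175Ter	stopgain	WD40	6713
1	c.3G>A	p.Met1Ile	startloss	-	31630
1	c.48+1G>C	-	splice site	coiled-coil	30260
1	c.49-1G>A	-	splice site	coiled-coil	689
1	c.103delC	p.Leu35PhefsTer18	frameshift deletion	coiled-coil	2758
1	c.173dupT	p.Leu58PhefsTer16	frameshift insertion	-	2554
1	c.178C>T	p.Gln60Ter	stopgain	-	6750
1	c.196C>T	p.Gln66Ter	stopgain	-	4158
1	c.428delT	p.Leu143ArgfsTer34	frameshift deletion	-	7178
1	c.451C>T	p.Gln151Ter	stopgain	-	8790
1	c.535C>T	p.Gln179Ter	stopgain	-	4885
1	c.940C>T	p.Gln314Ter	stopgain	-	1613
1	c.1027C>T	p.Gln343Ter	stopgain	-	2255
1	c.1174G>T	p.Glu392Ter	stopgain	-	4161
1	c.1257C>A	p.Cys419Ter	stopgain	ChAM	3900
1	c.1258C>T	p.Gln420Ter	stopgain	ChAM	725
1	c.1378C>T	p.Gln460Ter	stopgain	-	3440
1	c.1592delT	p.Leu531CysfsTer30	frameshift deletion	-	700
1	c.1969G>T	p.Glu657Ter	stopgain	-	2500
1	c.2066C>T	p.Ser689Leu	nonsynonymous SNV	-	6850
1	c.2386G>T	p.Gly796Ter	stopgain	-	1506
1	c.2389C>T	p.Gln797Ter	stopgain	-	4862
1	c.2594C>T	p.Ser865Leu	nonsynonymous SNV	WD40	4940
1	c.2674G>T	p.Glu892Ter	stopgain	WD40	8570
1	c.2674G>A	p.Glu892Lys	nonsynonymous SNV	WD40	3740
1	c.2694G>A	p.Trp898Ter	stopgain	WD40	>10000
1	c.2761C>T	p.Gln921Ter	stopgain	WD40	2478
1	c.2950dupC	p.Leu984ProfsTer3	frameshift insertion	WD40	7221
1	c.2962C>T	p.Gln988Ter	stopgain	WD40	1300
1	c.3058C>T	p.Gln1020Ter	stopgain	WD40	1246
1	c.3114-1G>A	-	splice site	WD40	2279
1	c.3113+1G>A	-	splice site	WD40	1646
1	c.3420G>A	p.Trp1140Ter	stopgain	WD40	1246
1	c.3469C>T	p.Gln1157Ter	stopgain	WD40	8315
1	c.3492G>A	p.Trp1164Ter	stopgain	WD40	18720
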