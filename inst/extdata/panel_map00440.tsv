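gene	ec	process
phnGHIL	2.7.8.37	phosphonate_degradation_cp_lyase
phnJ	4.7.1.1	phosphonate_degradation_cp_lyase
phnM	3.6.1.63	phosphonate_degradation_cp_lyase
phnN	2.7.4.23	phosphonate_degradation_cp_lyase
phnP	3.1.4.55	phosphonate_degradation_cp_lyase
phnO	2.3.1.280	phosphonate_degradation_cp_lyase
phnW	2.6.1.37	alternative_phosphonate_degradation
phnX	3.11.1.1	alternative_phosphonate_degradation
phnA	3.11.1.2	alternative_phosphonate_degradation
palA	3.11.1.3	alternative_phosphonate_degradation
phnY	1.14.11.46	alternative_phosphonate_degradation
phnZ	1.13.11.78	alternative_phosphonate_degradation
mpnS	1.13.11.73	alternative_phosphonate_degradation
ptxD	1.20.1.1	alternative_phosphonate_degradation
pepM	5.4.2.9	bialaphos_biosynthesis
ppd	4.1.1.82	bialaphos_biosynthesis
phpC	1.1.1.309	bialaphos_biosynthesis
phpD	1.13.11.72	bialaphos_biosynthesis
phpE	1.14.11.59	bialaphos_biosynthesis
phpI	2.7.8.23	bialaphos_biosynthesis
phpJ	1.2.1.101	bialaphos_biosynthesis
phpK	2.1.1.307	bialaphos_biosynthesis
pmmS	2.3.3.18	bialaphos_biosynthesis
PPT	2.3.1.183	bialaphos_biosynthesis
fom3	2.1.1.308	fr900098_biosynthesis
frbG	1.14.13.248	fr900098_biosynthesis
frbF	2.3.1.263	fr900098_biosynthesis
pss	2.7.8.8	phospholipid_biosynthesis
psd	4.1.1.65	phospholipid_biosynthesis
pcs	2.7.8.24	phospholipid_biosynthesis
aept	2.7.8.41	phospholipid_biosynthesis
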