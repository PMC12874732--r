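gene	ec	process
glnA	6.3.1.2	ammonium_assimilation
carAB	6.3.5.5	ammonium_assimilation
CPS1	6.3.4.16	ammonium_assimilation
gdhA	1.4.1.3	ammonium_assimilation
gltBD	1.4.1.13	glutamate_metabolism
gltBD	1.4.1.14	glutamate_metabolism
gltS	1.4.7.1	glutamate_metabolism
gudB	1.4.1.2	ammonium_release
gdh2	1.4.1.4	ammonium_release
glsA	3.5.1.2	ammonium_release
aspQ	3.5.1.38	ammonium_release
ureABC	3.5.1.5	ammonium_release
fmdA	3.5.1.49	ammonium_release
nit	3.5.5.1	ammonium_release
cynS	4.2.1.104	ammonium_release
can	4.2.1.1	ammonium_release
napAB	1.9.6.1	denitrification
nirKS	1.7.2.1	denitrification
norBC	1.7.2.5	denitrification
nosZ	1.7.2.4	denitrification
hmp	1.14.12.17	denitrification
hzsABC	1.7.2.7	denitrification
hdh	1.7.2.8	denitrification
narGZHYIV	1.7.5.1	dissimilatory_nitrate_reduction
nirBD	1.7.1.4	dissimilatory_nitrate_reduction
nrfAH	1.7.2.2	dissimilatory_nitrate_reduction
hcp	1.7.99.1	dissimilatory_nitrate_reduction
nirA	1.7.7.1	assimilatory_nitrate_reduction
narB	1.7.7.2	assimilatory_nitrate_reduction
nasA	1.7.1.1	assimilatory_nitrate_reduction
nasB	1.7.1.2	assimilatory_nitrate_reduction
NR	1.7.1.3	assimilatory_nitrate_reduction
NR2	1.7.1.15	assimilatory_nitrate_reduction
nifDKH	1.18.6.1	nitrogen_fixation
vnfDKG	1.19.6.1	nitrogen_fixation
pmoABC-amoABC	1.14.99.39	nitrification
hao	1.7.2.6	nitrification
nxrAB	1.7.99.4	nitrification
nmo	1.13.12.16	nitrification
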