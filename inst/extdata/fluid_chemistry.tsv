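borehole	analyte	species	value	unit
1025C	seafloor_depth	NA	2606.2	m
1025C	pressure	NA	26555	kPa
1025C	temperature	NA	39	C
1025C	pH	NA	7.9	pH
1025C	Mg	Mg++	29.7	mM
1025C	Ca	Ca++	30.4	mM
1025C	alkalinity	HCO3-	0.88	meq/L
1025C	NO3	NO3-	6.4	uM
1025C	NH4	NH4+	43	uM
1025C	SO4	SO4--	26.2	mM
1025C	Cl	Cl-	539	mM
1025C	Na	Na+	469	mM
1025C	K	K+	9.4	mM
1025C	Si	Si(aq)	590	uM
1025C	PO4	PO4---	0.05	uM
1025C	Fe3	Fe+++	1.3	uM
1025C	Fe2	Fe++	1.2	uM
1025C	Mn2	Mn++	1	uM
1025C	Mn4	Mn(IV)(aq)	1.2	uM
1025C	DOC	NA	22	uM
1025C	H2S	HS-	0	uM
U1301A	seafloor_depth	NA	2667.3	m
U1301A	pressure	NA	27071	kPa
U1301A	temperature	NA	63	C
U1301A	pH	NA	7.4	pH
U1301A	Mg	Mg++	1.9	mM
U1301A	Ca	Ca++	54	mM
U1301A	alkalinity	HCO3-	0.46	meq/L
U1301A	NO3	NO3-	0.3	uM
U1301A	NH4	NH4+	103	uM
U1301A	SO4	SO4--	17.2	mM
U1301A	Cl	Cl-	557	mM
U1301A	Na	Na+	471	mM
U1301A	K	K+	6.3	mM
U1301A	Si	Si(aq)	1166	uM
U1301A	PO4	PO4---	0.06	uM
U1301A	Fe3	Fe+++	0	uM
U1301A	Fe2	Fe++	0.9	uM
U1301A	Mn2	Mn++	4.1	uM
U1301A	Mn4	Mn(IV)(aq)	0.6	uM
U1301A	DOC	NA	13	uM
U1301A	H2S	HS-	0.17	uM
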