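species	charge	ion_size_A	note
H+	1	9.0	
OH-	-1	3.5	
Na+	1	4.0	
K+	1	3.0	
Cl-	-1	3.0	
Ca++	2	6.0	
Mg++	2	8.0	
SO4--	-2	4.0	
HCO3-	-1	4.5	alkalinity carrier
HS-	-1	3.5	sulfide below pH ~7 boundary treated as HS-
CH3COO-	-1	4.5	acetate, organic-matter proxy
NH4+	1	2.5	
NO3-	-1	3.0	
NO2-	-1	3.0	
PO4---	-3	4.0	
Fe++	2	6.0	
Fe+++	3	9.0	
Mn++	2	6.0	
Mn(IV)(aq)	0	0.0	particulate/colloidal Mn(IV), treated neutral
Si(aq)	0	0.0	silicic acid, neutral
CH4(aq)	0	0.0	
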