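component	class	group	table
Apc10	subunit	catalytic_arm	1
Apc11	subunit	catalytic_arm	1
Apc2	subunit	catalytic_arm	1
Apc1	subunit	structural_complex	1
Apc4	subunit	structural_complex	1
Apc5	subunit	structural_complex	1
Apc8	subunit	tpr_arm	1
Apc6	subunit	tpr_arm	1
Apc3	subunit	tpr_arm	1
Apc7	subunit	tpr_arm	1
Apc12	subunit	tpr_arm	1
Apc13	subunit	tpr_arm	1
Apc16	subunit	tpr_arm	1
Apc9	subunit	tpr_arm	1
Apc15	subunit	tpr_arm	1
Apc14	subunit	unassigned	1
Cdc20	adaptor	mitotic_adaptor	1
Cdh1	adaptor	mitotic_adaptor	1
Ama1	adaptor	meiotic_adaptor	1
Rap	adaptor	meiotic_adaptor	1
Cortex	adaptor	meiotic_adaptor	1
Mfr1	adaptor	meiotic_adaptor	NA
Smc1	target	cohesin_core	2
Smc3	target	cohesin_core	2
Scc1	target	cohesin_core	2
Scc3	target	cohesin_core	2
Scc2	target	cohesin_loading	2
Scc4	target	cohesin_loading	2
Eco1	target	cohesin_establishment	2
Pds5	target	cohesin_maintenance	2
Wpl1/Rad61	target	cohesin_maintenance	2
Separase	target	dissolution	2
Securin	target	dissolution	2
Cyclin_A	target	cyclin	NA
Cyclin_B	target	cyclin	NA
Cdk1	target	kinase	NA
Cdk2	target	kinase	NA
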