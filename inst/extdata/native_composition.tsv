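leaflet	species	count
inner	PLPE	2
inner	SLPE	2
inner	DLPE	2
inner	SAPE	8
inner	DAPE	2
inner	SDPE	4
inner	ODPE	2
inner	DDPE	2
inner	POPE	20
inner	DPPE	8
inner	SAPC	2
inner	POPC	8
inner	DPPC	4
inner	SLPS	2
inner	SAPS	4
inner	DAPS	1
inner	SDPS	2
inner	DDPS	1
inner	DSPS	6
inner	SOPS	8
inner	PSM	8
inner	SSM	4
inner	LSM	2
inner	BSM	2
inner	NSM	1
inner	CHOL	50
outer	PLPC	4
outer	SLPC	4
outer	OLPC	2
outer	LNSM	2
outer	SAPE	2
outer	SAPC	6
outer	SDPE	2
outer	SDPC	4
outer	DSM	2
outer	DLPC	1
outer	DAPC	2
outer	POPC	16
outer	DPPC	8
outer	POPE	4
outer	DPPE	2
outer	PSM	12
outer	SSM	6
outer	LSM	4
outer	BSM	4
outer	NSM	6
outer	CHOL	50
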