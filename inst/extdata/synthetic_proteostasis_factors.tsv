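list_name	sublist	gene
mito_proteostasis	chaperones	HSPA9
mito_proteostasis	chaperones	HSPD1
mito_proteostasis	chaperones	HSPE1
mito_proteostasis	chaperones	TRAP1
mito_proteostasis	chaperones	DNAJA3
mito_proteostasis	proteases	LONP1
mito_proteostasis	proteases	CLPP
mito_proteostasis	proteases	CLPX
mito_proteostasis	proteases	AFG3L2
mito_proteostasis	proteases	OMA1
mito_proteostasis	import	TIMM23
mito_proteostasis	import	TIMM23B
mito_proteostasis	import	TOMM22
mito_proteostasis	import	TOMM40
mito_proteostasis	import	PHB2
ER_proteostasis	chaperones	HSPA5
ER_proteostasis	chaperones	HSP90B1
ER_proteostasis	chaperones	CALR
ER_proteostasis	chaperones	CANX
ER_proteostasis	glycoproteostasis	DDOST
ER_proteostasis	glycoproteostasis	DAD1
ER_proteostasis	glycoproteostasis	STT3A
ER_proteostasis	targeting	SRP68
ER_proteostasis	targeting	SRP72
ER_proteostasis	targeting	SEC61A1
ER_proteostasis	degradation	SEL1L
ER_proteostasis	degradation	HRD1
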