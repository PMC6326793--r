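construct	base	observed_gv	observed_post_gvbd	figure_ref	note
Cpeb1-WT	Cpeb1	ACTIVE	UP	Fig 1C-E; Fig 3A-B	reporter translated in GV oocytes; signal rises further after meiotic resumption
Cpeb1-dPAS3	Cpeb1	ACTIVE	NA	Fig 1C-E	still translated with the distal PAS mutated; modest reduction
Cpeb1-dPAS1	Cpeb1	ACTIVE	NA	Fig 1C-E	translated at a reduced level when the proximal PAS is mutated
Cpeb1-dPAS2	Cpeb1	ACTIVE	NA	Fig 1C-E	mutation of the middle PAS leaves GV translation unaffected
Cpeb1-dPAS2/3	Cpeb1	ACTIVE	NA	Fig 1F-H	proximal PAS alone sustains roughly half of wild-type activity
Cpeb1-dPAS1/2	Cpeb1	ACTIVE	NA	Fig 1F-H	distal PAS alone sustains roughly half of wild-type activity
Cpeb1-dPAS1/3	Cpeb1	SILENT	UP	Fig 1F-H; Fig 3F-G	middle PAS alone does not support GV translation; activated after release from arrest
Cpeb1-dPAS1/2/3	Cpeb1	SILENT	NA	Fig 1F-H	no intact PAS, no GV translation
Cpeb1-dCPE1-4	Cpeb1	ACTIVE	NA	Fig 3A-B	CPE mutation slightly raises GV translation; smaller gain at MII
Cpeb1-dPAS1/3+dCPE1-4	Cpeb1	ACTIVE	NA	Fig 3C-D	mutating the four flanking CPEs restores middle-PAS translation
Cpeb1-dPAS1/3+dCPE1/2	Cpeb1	PARTIAL	NA	Fig 4A-B	mutating the two same-side CPEs partially de-represses the middle PAS
Cpeb1-dPAS1/3+dCPE2/4	Cpeb1	SILENT	NA	Fig 4A-B	mutating one CPE on each side gives only marginal de-repression
Cpeb1-dPAS2/3+dCPE1-4	Cpeb1	ACTIVE	NA	Fig 4C-D	CPE status does not change proximal-PAS translation at either stage
Cpeb1-spacer-50	Cpeb1	ACTIVE	NA	Fig 4E-F	50-nt spacer between the proximal PAS and the nearest CPE leaves translation unaffected
Cpeb1-spacer-35	Cpeb1	PARTIAL	NA	Fig 4E-F	shortening the spacer to 35 nt impairs proximal-PAS translation
Cpeb1-spacer-15	Cpeb1	PARTIAL	NA	Fig 4E-F	15-nt spacer impairs proximal-PAS translation
Cpeb1-insert-CPE-35	Cpeb1	PARTIAL	NA	Supplementary (Fig 4 series)	a CPE inserted 35 nt downstream of the free PAS inhibits its translation
Cpeb1-insert-CPE-50	Cpeb1	ACTIVE	NA	Supplementary (Fig 4 series)	a CPE inserted 50 nt downstream has no inhibitory effect
Cpeb1-dPBE	Cpeb1	ACTIVE	UP	Supplementary (Fig 4 series)	removing the single PBE does not prevent the post-GVBD increase
Btg4-WT	Btg4	SILENT	UP	Fig 5B-C	dormant in GV oocytes; translated after meiotic resumption
Btg4-dCPE1	Btg4	SILENT	NA	Fig 5F-G	mutating the far upstream CPE gives only marginal de-repression
Btg4-dCPE2	Btg4	SILENT	NA	Fig 5F-G	mutating the near upstream CPE gives only marginal de-repression
Btg4-dCPE3	Btg4	ACTIVE	NA	Fig 5F-G	mutating the downstream CPE de-represses clearly
Btg4-dCPE1/3	Btg4	ACTIVE	NA	Fig 5F-G	double CPE mutation de-represses further
Btg4-dCPE1/2	Btg4	ACTIVE	NA	Fig 5F-G	double CPE mutation de-represses further
Btg4-dCPE1/2/3	Btg4	ACTIVE	NA	Fig 5B-C	triple CPE mutation fully de-represses GV translation
Cnot6l-WT	Cnot6l	ACTIVE	UP	Fig 6B-C	full-length UTR translated in GV oocytes; translation increases after GVBD
Cnot6l-dPAS1	Cnot6l	SILENT	UP	Fig 6B-C; Fig 6H-I	proximal-PAS mutation abolishes GV translation; restored after meiotic resumption
Cnot6l-dPAS2	Cnot6l	ACTIVE	NA	Fig 6B-C	distal-PAS mutation does not affect GV translation
Cnot6l-dPAS1+dCPE4	Cnot6l	ACTIVE	NA	Fig 6F-G	mutating the CPE adjacent to the distal PAS restores its translation
Cnot6l-dPAS1+dCPE2/3	Cnot6l	SILENT	NA	Fig 6F-G	mutating the two distant CPEs fails to relieve the distal PAS from dormancy
Cnot6l-trunc-402	Cnot6l	SILENT	UP	Fig 6A (402-nt fragment)	distal 402-nt fragment is dormant in GV oocytes and activated after resumption
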