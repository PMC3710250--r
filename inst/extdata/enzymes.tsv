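# Built-in restriction enzyme catalog: NAME<TAB>SITE with one caret marking
# the cut position. Blunt-end frequent cutters plus the sticky-end enzymes
# screened for the hsp60 assay. Recognition sites are standard catalog data.
HaeIII	GG^CC
RsaI	GT^AC
AluI	AG^CT
AccII	CG^CG
Sau3AI	^GATC
AatII	GACGT^C
PvuI	CGAT^CG
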