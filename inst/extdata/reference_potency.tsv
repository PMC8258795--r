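# In-vitro LRRK2 G2019S potency of the screened candidates (IC50) and
# competitive binding (Kd), in nM, with comparator flags for censored
# measurements (">" = above assay ceiling, "<" = below quantification).
# Provenance note: the source table prints the Vardenafil IC50 as "470,00";
# the accompanying text states 47 uM twice, so 47000 nM is stored here.
compound	role	ic50_nM	ic50_cmp	kd_nM	kd_cmp
Vardenafil	candidate	47000	=	100000	>
Paroxetine	candidate	100000	>	100000	>
Efavirenz	candidate	100000	>	100000	>
Crizotinib	candidate	980	=	8300	=
Liothyronine	candidate	67000	=	100000	>
Sunitinib	candidate	10	=	67	=
GW5074	control	5.1	<	790	=
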