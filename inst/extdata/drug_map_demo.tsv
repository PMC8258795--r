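# Demonstration het-code -> approved-drug map. Curated entries reflect the
# PDB chemical component dictionary to the maintainers' best knowledge and
# make no claim of completeness; verify codes before production use.
# Synthetic codes (provenance "synthetic") are used by the built-in
# generator and pipeline examples.
het_code	drug_name	approved	provenance
VGH	Crizotinib	TRUE	curated
B49	Sunitinib	TRUE	curated
VDN	Vardenafil	TRUE	curated
EFZ	Efavirenz	TRUE	curated
T3	Liothyronine	TRUE	curated
PLT	PlantedDemoDrug	TRUE	synthetic
LIG	SyntheticTestDrug	TRUE	synthetic
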