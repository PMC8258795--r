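# Queries and top hits of the structure-based screen: query complex,
# hit complex (PDB id), drug, approved use, predicted blood-brain-barrier
# permeability.
query_pdb	query_compound	hit_pdb	drug_name	approved_use	bbb_permeable
4YZM	LRRK2-IN-1	1XP0	Vardenafil	phosphodiesterase 5A inhibitor (erectile dysfunction)	TRUE
4YZM	LRRK2-IN-1	4L9I	Paroxetine	serotonin uptake inhibitor (depression)	TRUE
4YZM	LRRK2-IN-1	1IKW	Efavirenz	non-nucleoside reverse-transcriptase inhibitor (HIV/AIDS)	TRUE
4YZM	LRRK2-IN-1	4ANS	Crizotinib	mutant ALK inhibitor (oncology)	FALSE
4YZN	Compound19	3VKX	Liothyronine	synthetic thyroid hormone (hypothyroidism)	TRUE
4YZN	Compound19	3MIY	Sunitinib	receptor tyrosine kinase inhibitor (oncology)	TRUE
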