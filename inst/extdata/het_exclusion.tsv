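het_code	reason
HOH	water
DOD	heavy water
NA	sodium ion
K	potassium ion
CL	chloride ion
MG	magnesium ion
CA	calcium ion
ZN	zinc ion
MN	manganese ion
FE	iron ion
FE2	iron(II) ion
CU	copper ion
NI	nickel ion
CO	cobalt ion
CD	cadmium ion
HG	mercury ion
LI	lithium ion
BR	bromide ion
IOD	iodide ion
SO4	sulfate (buffer)
PO4	phosphate (buffer)
NO3	nitrate (buffer)
GOL	glycerol (cryoprotectant)
EDO	ethylene glycol (cryoprotectant)
PEG	di(hydroxyethyl)ether (PEG fragment)
PG4	tetraethylene glycol (PEG fragment)
P6G	hexaethylene glycol (PEG fragment)
MPD	2-methyl-2,4-pentanediol (cryoprotectant)
DMS	dimethyl sulfoxide (solvent)
ACT	acetate (buffer)
FMT	formate (buffer)
ACY	acetic acid (buffer)
CIT	citrate (buffer)
TRS	tris buffer
EPE	HEPES buffer
MES	MES buffer
IMD	imidazole (buffer)
BME	beta-mercaptoethanol (reductant)
DTT	dithiothreitol (reductant)
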