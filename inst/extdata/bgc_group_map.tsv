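family	group
T1PKS	PKS
T2PKS	PKS
T3PKS	PKS
transAT-PKS	PKS
transAT-PKS-like	PKS
PKS-like	PKS
PpyS-KS	PKS
hglE-KS	PKS
arylpolyene	PKS
ladderane	PKS
PUFA	PKS
NRPS-T1PKS	PKS
NRPS	NRPS
NRPS-like	NRPS
CDPS	NRPS
thioamide-NRP	NRPS
NAPAA	NRPS
terpene	terpene
lanthipeptide	RiPP
lantipeptide	RiPP
lanthipeptide-class-i	RiPP
lanthipeptide-class-ii	RiPP
lanthipeptide-class-iii	RiPP
lanthipeptide-class-iv	RiPP
lanthipeptide-class-v	RiPP
lipolanthine	RiPP
linaridin	RiPP
cyanobactin	RiPP
glycocin	RiPP
LAP	RiPP
lassopeptide	RiPP
microviridin	RiPP
proteusin	RiPP
sactipeptide	RiPP
ranthipeptide	RiPP
bottromycin	RiPP
head_to_tail	RiPP
microcin	RiPP
thiopeptide	RiPP
bacteriocin	RiPP
RiPP-like	RiPP
RaS-RiPP	RiPP
fungal-RiPP	RiPP
thioamitides	RiPP
redox-cofactor	RiPP
ectoine	AAmodifier
NAGGN	AAmodifier
betalactone	AAmodifier
butyrolactone	AAmodifier
hserlactone	other
phosphonate	other
siderophore	other
melanin	other
indole	other
furan	other
resorcinol	other
acyl_amino_acids	AAmodifier
aminocoumarin	other
oligosaccharide	other
amglyccycl	other
nucleoside	other
phenazine	other
phosphoglycolipid	other
PBDE	other
tropodithietic-acid	other
CDPS-like	NRPS
other	other
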