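# Default chemical-component map: component_id -> (category, modification_class).
# Ids follow the wwPDB chemical component dictionary (CCD). Most are standard
# and stable (PSU, OMC/OMG/OMU/A2M, 1MA, 5MC, 6MZ, UR3, MLZ, SPM/SPD/PUT, MG,
# K, HOH). Three are candidate ids that could not be cross-checked against the
# CCD here and MUST be verified against the target entry before production use:
#   M4C  (N4-methylcytidine)            -- candidate id
#   PSM  (2'-O-methylpseudouridine)     -- candidate id; some entries encode
#                                          this base as PSU plus an annotation,
#                                          which the 'combined' class also covers
#   HBH  (beta-hydroxy-histidine, 2S,3S)-- candidate id
# The file is an editable package resource; pass your own copy to
# read_component_map()/classify_components() to override any row.
# The 'combined' class marks one residue contributing to BOTH the
# pseudouridine and ribose-2prime-O-methyl tallies.
component_id	category	modification_class
PSU	modified-ribonucleotide	pseudouridine
PSM	modified-ribonucleotide	combined
OMA	modified-ribonucleotide	ribose-2prime-O-methyl
A2M	modified-ribonucleotide	ribose-2prime-O-methyl
OMC	modified-ribonucleotide	ribose-2prime-O-methyl
OMG	modified-ribonucleotide	ribose-2prime-O-methyl
OMU	modified-ribonucleotide	ribose-2prime-O-methyl
1MA	modified-ribonucleotide	m1A
M4C	modified-ribonucleotide	m4C
5MC	modified-ribonucleotide	m5C
6MZ	modified-ribonucleotide	m6A
UR3	modified-ribonucleotide	m3U
HBH	modified-amino-acid	beta-hydroxy-histidine
HIC	modified-amino-acid	tau-N-methyl-histidine
MLZ	modified-amino-acid	epsilon-N-methyl-lysine
SPM	polyamine	NA
SPD	polyamine	NA
PUT	polyamine	NA
MG	metal	NA
K	metal	NA
NA	metal	NA
ZN	metal	NA
MN	metal	NA
CA	metal	NA
HOH	water	NA
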