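# Residue atom -> united-atom nonbonded class. "*" rows are the generic
# backbone mapping applied to every residue type.
# res_type atom_name class
*   N    NAM
*   H    HN
*   CA   CH1A
*   C    CO
*   O    OCB
*   OXT  OC2
ALA CB   CH3
SER CB   CH2
SER OG   OHX
SER HG   HP
CYS CB   CH2
CYS SG   SHG
THR CB   CH1
THR OG1  OHX
THR HG1  HP
THR CG2  CH3
VAL CB   CH1
VAL CG1  CH3
VAL CG2  CH3
ILE CB   CH1
ILE CG1  CH2
ILE CG2  CH3
ILE CD1  CH3
LEU CB   CH2
LEU CG   CH1
LEU CD1  CH3
LEU CD2  CH3
ASN CB   CH2
ASN CG   CO
ASN OD1  OCB
ASN ND2  NAM
ASP CB   CH2
ASP CG   CO2
ASP OD1  OC2
ASP OD2  OC2
GLN CB   CH2
GLN CG   CH2
GLN CD   CO
GLN OE1  OCB
GLN NE2  NAM
GLU CB   CH2
GLU CG   CH2
GLU CD   CO2
GLU OE1  OC2
GLU OE2  OC2
MET CB   CH2
MET CG   CH2
MET SD   SM
MET CE   CH3
LYS CB   CH2
LYS CG   CH2
LYS CD   CH2
LYS CE   CH2B
LYS NZ   NZ3
ARG CB   CH2
ARG CG   CH2
ARG CD   CH2B
ARG NE   NEA
ARG CZ   CGU
ARG NH1  NHG
ARG NH2  NHG
HIS CB   CH2
HIS CG   CJ
HIS ND1  NAR
HIS CD2  CAR
HIS CE1  CAR
HIS NE2  NAR
HIS HD1  HP
HIS HE2  HP
PHE CB   CH2
PHE CG   CJ
PHE CD1  CAR
PHE CD2  CAR
PHE CE1  CAR
PHE CE2  CAR
PHE CZ   CAR
TYR CB   CH2
TYR CG   CJ
TYR CD1  CAR
TYR CD2  CAR
TYR CE1  CAR
TYR CE2  CAR
TYR CZ   CJ
TYR OH   OHX
TYR HH   HP
TRP CB   CH2
TRP CG   CJ
TRP CD1  CAR
TRP CD2  CJ
TRP NE1  NAR
TRP CE2  CJ
TRP CE3  CAR
TRP CZ2  CAR
TRP CZ3  CAR
TRP CH2  CAR
PRO CB   CH2
PRO CG   CH2
PRO CD   CH2
HOH O    OW
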