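res_type chi1 chi2 chi3 chi4 probability
SER -60 . . . 0.45
SER 180 . . . 0.35
SER  60 . . . 0.2
CYS -60 . . . 0.45
CYS 180 . . . 0.35
CYS  60 . . . 0.2
THR -60 . . . 0.45
THR 180 . . . 0.35
THR  60 . . . 0.2
VAL -60 . . . 0.45
VAL 180 . . . 0.35
VAL  60 . . . 0.2
ILE -60 -60 . . 0.2025
ILE 180 -60 . . 0.1575
ILE  60 -60 . . 0.09
ILE -60 180 . . 0.1575
ILE 180 180 . . 0.1225
ILE  60 180 . . 0.07
ILE -60  60 . . 0.09
ILE 180  60 . . 0.07
ILE  60  60 . . 0.04
LEU -60 -60 . . 0.2025
LEU 180 -60 . . 0.1575
LEU  60 -60 . . 0.09
LEU -60 180 . . 0.1575
LEU 180 180 . . 0.1225
LEU  60 180 . . 0.07
LEU -60  60 . . 0.09
LEU 180  60 . . 0.07
LEU  60  60 . . 0.04
ASN -60 -60 . . 0.18
ASN 180 -60 . . 0.14
ASN  60 -60 . . 0.08
ASN -60  60 . . 0.1575
ASN 180  60 . . 0.1225
ASN  60  60 . . 0.07
ASN -60 180 . . 0.1125
ASN 180 180 . . 0.0875
ASN  60 180 . . 0.05
ASP -60 -30 . . 0.18
ASP 180 -30 . . 0.14
ASP  60 -30 . . 0.08
ASP -60  30 . . 0.1575
ASP 180  30 . . 0.1225
ASP  60  30 . . 0.07
ASP -60  80 . . 0.1125
ASP 180  80 . . 0.0875
ASP  60  80 . . 0.05
GLN -60 -60 -60 . 0.081
GLN 180 -60 -60 . 0.063
GLN  60 -60 -60 . 0.036
GLN -60 180 -60 . 0.063
GLN 180 180 -60 . 0.049
GLN  60 180 -60 . 0.028
GLN -60  60 -60 . 0.036
GLN 180  60 -60 . 0.028
GLN  60  60 -60 . 0.016
GLN -60 -60  60 . 0.070875
GLN 180 -60  60 . 0.055125
GLN  60 -60  60 . 0.0315
GLN -60 180  60 . 0.055125
GLN 180 180  60 . 0.042875
GLN  60 180  60 . 0.0245
GLN -60  60  60 . 0.0315
GLN 180  60  60 . 0.0245
GLN  60  60  60 . 0.014
GLN -60 -60 180 . 0.050625
GLN 180 -60 180 . 0.039375
GLN  60 -60 180 . 0.0225
GLN -60 180 180 . 0.039375
GLN 180 180 180 . 0.030625
GLN  60 180 180 . 0.0175
GLN -60  60 180 . 0.0225
GLN 180  60 180 . 0.0175
GLN  60  60 180 . 0.01
GLU -60 -60 -30 . 0.081
GLU 180 -60 -30 . 0.063
GLU  60 -60 -30 . 0.036
GLU -60 180 -30 . 0.063
GLU 180 180 -30 . 0.049
GLU  60 180 -30 . 0.028
GLU -60  60 -30 . 0.036
GLU 180  60 -30 . 0.028
GLU  60  60 -30 . 0.016
GLU -60 -60  30 . 0.070875
GLU 180 -60  30 . 0.055125
GLU  60 -60  30 . 0.0315
GLU -60 180  30 . 0.055125
GLU 180 180  30 . 0.042875
GLU  60 180  30 . 0.0245
GLU -60  60  30 . 0.0315
GLU 180  60  30 . 0.0245
GLU  60  60  30 . 0.014
GLU -60 -60  80 . 0.050625
GLU 180 -60  80 . 0.039375
GLU  60 -60  80 . 0.0225
GLU -60 180  80 . 0.039375
GLU 180 180  80 . 0.030625
GLU  60 180  80 . 0.0175
GLU -60  60  80 . 0.0225
GLU 180  60  80 . 0.0175
GLU  60  60  80 . 0.01
MET -60 -60 -60 . 0.091125
MET 180 -60 -60 . 0.070875
MET  60 -60 -60 . 0.0405
MET -60 180 -60 . 0.070875
MET 180 180 -60 . 0.055125
MET  60 180 -60 . 0.0315
MET -60  60 -60 . 0.0405
MET 180  60 -60 . 0.0315
MET  60  60 -60 . 0.018
MET -60 -60 180 . 0.111375
MET 180 -60 180 . 0.086625
MET  60 -60 180 . 0.0495
MET -60 180 180 . 0.086625
MET 180 180 180 . 0.067375
MET  60 180 180 . 0.0385
MET -60  60 180 . 0.0495
MET 180  60 180 . 0.0385
MET  60  60 180 . 0.022
LYS -60 -60 -60 -60 0.04100625
LYS 180 -60 -60 -60 0.03189375
LYS  60 -60 -60 -60 0.018225
LYS -60 180 -60 -60 0.03189375
LYS 180 180 -60 -60 0.02480625
LYS  60 180 -60 -60 0.014175
LYS -60  60 -60 -60 0.018225
LYS 180  60 -60 -60 0.014175
LYS  60  60 -60 -60 0.0081
LYS -60 -60 180 -60 0.05011875
LYS 180 -60 180 -60 0.03898125
LYS  60 -60 180 -60 0.022275
LYS -60 180 180 -60 0.03898125
LYS 180 180 180 -60 0.03031875
LYS  60 180 180 -60 0.017325
LYS -60  60 180 -60 0.022275
LYS 180  60 180 -60 0.017325
LYS  60  60 180 -60 0.0099
LYS -60 -60 -60 180 0.05011875
LYS 180 -60 -60 180 0.03898125
LYS  60 -60 -60 180 0.022275
LYS -60 180 -60 180 0.03898125
LYS 180 180 -60 180 0.03031875
LYS  60 180 -60 180 0.017325
LYS -60  60 -60 180 0.022275
LYS 180  60 -60 180 0.017325
LYS  60  60 -60 180 0.0099
LYS -60 -60 180 180 0.06125625
LYS 180 -60 180 180 0.04764375
LYS  60 -60 180 180 0.027225
LYS -60 180 180 180 0.04764375
LYS 180 180 180 180 0.03705625
LYS  60 180 180 180 0.021175
LYS -60  60 180 180 0.027225
LYS 180  60 180 180 0.021175
LYS  60  60 180 180 0.0121
ARG -60 -60 -60 -60 0.04100625
ARG 180 -60 -60 -60 0.03189375
ARG  60 -60 -60 -60 0.018225
ARG -60 180 -60 -60 0.03189375
ARG 180 180 -60 -60 0.02480625
ARG  60 180 -60 -60 0.014175
ARG -60  60 -60 -60 0.018225
ARG 180  60 -60 -60 0.014175
ARG  60  60 -60 -60 0.0081
ARG -60 -60 180 -60 0.05011875
ARG 180 -60 180 -60 0.03898125
ARG  60 -60 180 -60 0.022275
ARG -60 180 180 -60 0.03898125
ARG 180 180 180 -60 0.03031875
ARG  60 180 180 -60 0.017325
ARG -60  60 180 -60 0.022275
ARG 180  60 180 -60 0.017325
ARG  60  60 180 -60 0.0099
ARG -60 -60 -60 180 0.05011875
ARG 180 -60 -60 180 0.03898125
ARG  60 -60 -60 180 0.022275
ARG -60 180 -60 180 0.03898125
ARG 180 180 -60 180 0.03031875
ARG  60 180 -60 180 0.017325
ARG -60  60 -60 180 0.022275
ARG 180  60 -60 180 0.017325
ARG  60  60 -60 180 0.0099
ARG -60 -60 180 180 0.06125625
ARG 180 -60 180 180 0.04764375
ARG  60 -60 180 180 0.027225
ARG -60 180 180 180 0.04764375
ARG 180 180 180 180 0.03705625
ARG  60 180 180 180 0.021175
ARG -60  60 180 180 0.027225
ARG 180  60 180 180 0.021175
ARG  60  60 180 180 0.0121
HIS -60  80 . . 0.18
HIS 180  80 . . 0.14
HIS  60  80 . . 0.08
HIS -60 -80 . . 0.18
HIS 180 -80 . . 0.14
HIS  60 -80 . . 0.08
HIS -60   0 . . 0.09
HIS 180   0 . . 0.07
HIS  60   0 . . 0.04
PHE -60  80 . . 0.18
PHE 180  80 . . 0.14
PHE  60  80 . . 0.08
PHE -60 -80 . . 0.18
PHE 180 -80 . . 0.14
PHE  60 -80 . . 0.08
PHE -60   0 . . 0.09
PHE 180   0 . . 0.07
PHE  60   0 . . 0.04
TYR -60  80 . . 0.18
TYR 180  80 . . 0.14
TYR  60  80 . . 0.08
TYR -60 -80 . . 0.18
TYR 180 -80 . . 0.14
TYR  60 -80 . . 0.08
TYR -60   0 . . 0.09
TYR 180   0 . . 0.07
TYR  60   0 . . 0.04
TRP -60  90 . . 0.2475
TRP 180  90 . . 0.1925
TRP  60  90 . . 0.11
TRP -60 -90 . . 0.2025
TRP 180 -90 . . 0.1575
TRP  60 -90 . . 0.09
PRO  28 -35 . . 0.25
PRO -28 -35 . . 0.25
PRO  28  35 . . 0.25
PRO -28  35 . . 0.25
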