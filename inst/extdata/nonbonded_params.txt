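# United-atom nonbonded parameter classes (OPLS-style united-atom scheme:
# nonpolar hydrogens implicit, polar hydrogens explicit with zero LJ).
# Values assembled for this package from standard united-atom conventions.
# class  sigma_A  epsilon_kcal  charge_e
CH3   3.905 0.175  0.000
CH2   3.905 0.118  0.000
CH1   3.850 0.080  0.000
CH2B  3.905 0.118  0.250
CH1A  3.850 0.080  0.200
CAR   3.750 0.110  0.000
CJ    3.750 0.070  0.000
CO    3.750 0.105  0.500
CO2   3.750 0.105  0.700
CGU   3.750 0.050  0.640
OCB   2.960 0.210 -0.500
OC2   2.960 0.210 -0.800
OHX   3.070 0.170 -0.700
NAM   3.250 0.170 -0.570
NAR   3.250 0.170 -0.490
NZ3   3.250 0.170  0.800
NEA   3.250 0.170 -0.260
NHG   3.250 0.170  0.450
SHG   3.550 0.250 -0.200
SM    3.550 0.250  0.000
HP    0.000 0.000  0.435
HN    0.000 0.000  0.370
OW    3.150 0.152 -0.800
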