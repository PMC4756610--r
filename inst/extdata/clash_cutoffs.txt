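# Minimum allowed heavy-atom contact distances by element pair, Angstrom,
# derived for this package from van der Waals radii (sum - 0.6 A, the
# shortest contacts seen in well-refined structures). The user-adjustable
# reduction (default 0.3 A) is applied on top of these values.
# elem_a elem_b min_dist
C C 2.80
C N 2.65
C O 2.62
C S 2.90
C P 2.90
N N 2.50
N O 2.47
N S 2.75
N P 2.75
O O 2.44
O S 2.72
O P 2.72
S S 3.00
S P 3.00
P P 3.00
H C 2.30
H N 2.15
H O 2.12
H S 2.40
H H 1.80
H P 2.40
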