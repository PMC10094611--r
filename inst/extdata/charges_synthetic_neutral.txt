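# Synthetic partial-charge set for the toy CRO-style chromophore fragment.
# NOT a force-field parameterization: values are invented (force-field-like
# magnitudes) and sum exactly to 0 e, so the fragment dipole moment is
# origin-independent.  Units: elementary charge.
C1    0.50
N2   -0.35
N3   -0.20
C2    0.50
O2   -0.45
CA2   0.00
CB2  -0.05
CG2   0.00
CD1  -0.05
CD2  -0.05
CE1  -0.05
CE2  -0.05
CZ    0.30
OH   -0.45
HOH1  0.40
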