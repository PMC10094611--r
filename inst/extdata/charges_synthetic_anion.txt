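# Synthetic partial-charge set for the toy chromophore fragment in a
# phenolate-like (deprotonated) state.  NOT a force-field parameterization:
# values are invented and sum exactly to -1 e, to exercise the
# reference-point dependence of the dipole moment for a charged fragment.
# The hydroxyl proton entry is zero (no proton in this state).
# Units: elementary charge.
C1    0.40
N2   -0.20
N3   -0.05
C2    0.50
O2   -0.50
CA2   0.10
CB2   0.00
CG2   0.00
CD1  -0.20
CD2  -0.20
CE1  -0.25
CE2  -0.25
CZ    0.45
OH   -0.80
HOH1  0.00
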