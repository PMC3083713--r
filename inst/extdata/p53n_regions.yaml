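# Default rotamer-region sets and bound-reference conformations for the
# p53N peptide (Glu17-Asn29). Intervals are circular half-open [lo, hi)
# in degrees; lo > hi wraps through +/-180.
#
# The Phe19 chi1 regions (A/B/C) and the six Trp23 chi1 x chi2 regions
# are the three canonical chi1 wells (t / g- / g+), for Trp23 split by
# the sign of chi2. Region bounds are configuration, not code: they are
# this package's estimate of the state partition of the p53N ensembles
# and can be replaced by the user.
#
# Bound-reference angles: Phe19 in the MDM2 complex is the literature
# value (chi1 177, chi2 71). The remaining references are SYNTHETIC
# stand-in values chosen inside the rotamer well that each complex
# selects; replace them with values measured from real complex
# structures where available. Phe chi2 is symmetry-folded to [-90, 90).
tolerance: 40
regions:
  "19":
    labels: [A, B, C]
    chi1:
      A: [120, -120]   # trans well, contains the MDM2-bound chi1 = 177
      B: [-120, 0]     # gauche-
      C: [0, 120]      # gauche+
  "23":
    labels: ["1", "2", "3", "4", "5", "6"]
    chi1:
      "1": [120, -120]
      "2": [120, -120]
      "3": [-120, 0]
      "4": [-120, 0]
      "5": [0, 120]
      "6": [0, 120]
    chi2:
      "1": [0, 180]    # contains the MDM2-bound Trp23 reference
      "2": [-180, 0]
      "3": [0, 180]
      "4": [-180, 0]
      "5": [0, 180]
      "6": [-180, 0]
boundReferences:
  - {resno: 19, complex: p53N-MDM2, chi1: 177, chi2: 71, role: anchor-type}
  - {resno: 19, complex: p53N-Taz2, chi1: -65, chi2: -80, role: non-anchor, synthetic: true}
  - {resno: 22, complex: p53N-Taz2, chi1: -65, chi2: 175, role: anchor-type, synthetic: true}
  - {resno: 22, complex: p53N-MDM2, chi1: 180, chi2: 65, role: non-anchor, synthetic: true}
  - {resno: 23, complex: p53N-MDM2, chi1: 180, chi2: 90, role: anchor-type, synthetic: true}
  - {resno: 23, complex: p53N-Taz2, chi1: -65, chi2: 95, role: non-anchor, synthetic: true}
  - {resno: 26, complex: p53N-MDM2, chi1: -65, chi2: 175, role: anchor-type, synthetic: true}
  - {resno: 26, complex: p53N-Taz2, chi1: 65, chi2: -60, role: non-anchor, synthetic: true}
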