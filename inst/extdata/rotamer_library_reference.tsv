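# Backbone-independent rotamer-library populations (percent) of the
# bound-like side-chain conformations of the four p53N anchor residues.
# role: anchor-type = conformation seen in the complex where the residue
# is an anchor (MDM2 for Phe19/Trp23/Leu26, Taz2 for Leu22); non-anchor =
# conformation seen in the alternative complex. qualifier "<" marks an
# upper bound ("below 1 percent" in the source library).
resno	resname	role	libraryPct	qualifier
19	PHE	anchor-type	31.71
19	PHE	non-anchor	47.08
22	LEU	anchor-type	62.52
22	LEU	non-anchor	3.65
23	TRP	anchor-type	16.21
23	TRP	non-anchor	5.32
26	LEU	anchor-type	62.52
26	LEU	non-anchor	1	<
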