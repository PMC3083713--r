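# Reference trajectory table for the p53N helix-unfolding worked example:
# explicit-solvent MD trajectories of the unbound p53N peptide started
# from the MDM2-bound helix (MS1-MS10), the Taz2-bound helix (TS1-TS5) or
# disordered snapshots (DS1-DS5). unfoldingTimeNs NA = started disordered.
trajectory	group	durationNs	unfoldingTimeNs
MS1	MDM2-helix	100	43
MS2	MDM2-helix	20	11
MS3	MDM2-helix	100	42
MS4	MDM2-helix	100	25
MS5	MDM2-helix	20	17
MS6	MDM2-helix	60	28
MS7	MDM2-helix	20	10
MS8	MDM2-helix	20	15
MS9	MDM2-helix	60	23
MS10	MDM2-helix	60	31
TS1	Taz2-helix	20	2
TS2	Taz2-helix	20	4
TS3	Taz2-helix	20	3
TS4	Taz2-helix	20	9
TS5	Taz2-helix	20	8
DS1	disordered	50	NA
DS2	disordered	50	NA
DS3	disordered	50	NA
DS4	disordered	50	NA
DS5	disordered	50	NA
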