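---
title: "IDPAnchor: methods, parameters and design choices"
author: "IDPAnchor authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IDPAnchor: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IDPAnchor)
```

# Scope and model

`IDPAnchor` analyses how an intrinsically disordered peptide's unbound
conformational ensemble relates to its bound poses, using the p53
transactivation peptide p53N (Glu17--Asn29, `ETFSDLWKLLPEN`) as the
worked system. Three quantities carry the analysis:

1. **Anchor residues** from SASA burial. A residue is an anchor in a
   given complex when it is solvent-exposed in the unbound reference and
   essentially fully buried in the complex. The burial cutoff,
   15 Å² per residue, is the literature convention for "fully buried".
   The exposure cutoff is not standardised anywhere we know of; this
   package uses 30 Å² (roughly a fifth of a typical exposed side chain)
   and echoes it into every report so the choice is auditable. Two
   unbound references are supported: the peptide extracted from the
   complex in its bound conformation (default), or the mean over an
   unbound ensemble. Classification may use total per-residue SASA
   (default, matching how per-residue SASA bars are usually drawn) or
   side-chain-only SASA.

2. **Bound-like rotamer populations.** Side-chain states are described
   by the first two torsions, χ₁ = N--Cα--Cβ--Cγ and
   χ₂ = Cα--Cβ--Cγ--Cδ₁ (Cδ₁ for Phe/Trp/Leu; no alternative-atom
   fallback). Populations are computed two ways: membership in named
   circular regions (a disjoint partition of χ space, so fractions plus
   an "unassigned" class sum to one exactly), and matching of a
   *bound reference* conformation within a circular per-angle tolerance.

3. **Helix state.** The peptide's transient helix (Thr18--Leu26) is
   assigned by a simplified two-criterion rule, and each trajectory is
   split at its unfolding time into helix-state and disordered-state
   frames, over which populations are reported separately.

# Geometric conventions

Torsions are reported in degrees in (−180, 180], IUPAC sign (positive =
clockwise looking from the second toward the third atom). The sign
convention is pinned by tests against an independent rotation-matrix
construction and against `bio3d::torsion.xyz`. Missing atoms yield
explicit `NA` angles — never 0 — and such frames leave the denominators
of every population.

Phe (and Tyr) χ₂ is 180°-periodic because the ring flip is a symmetry
operation; all Phe/Tyr χ₂ values are folded into [−90, 90) before any
region test or population count. Trp is not folded: the indole is
asymmetric.

Superposition is unweighted Kabsch least-squares (SVD with reflection
rejection). The RMSD window for the p53N helix defaults to Phe19--Leu26
backbone (N, Cα, C, O); the helix-content window defaults to
Thr18--Leu26. Both windows appear in the literature for this system and
both are parameters.

# The SASA engine

Shrake--Rupley with a deterministic Fibonacci (golden-angle) lattice,
960 points per atom by default; no random numbers are involved, so
results are exactly reproducible and the isolated-sphere case reproduces
4π(r+probe)² to machine precision (the lattice weights are uniform).
Radii are NACCESS-style element radii (C 1.87, N 1.65, O 1.40, S 1.85,
P 1.80 Å); probe 1.4 Å; hydrogens are excluded as surface atoms and as
occluders (the NACCESS convention), with a flag to include them. The
engine is validated against the analytic two-sphere spherical-cap
formula (< 2 % at 960 points) and against an independent Monte-Carlo
surface-sampling oracle (agreement within the oracle's sampling error;
the per-atom comparison uses a 4σ bound because ~24 atoms are tested
jointly). Because the lattice is fixed in space, SASA is only
approximately rotation-invariant; on the 13-mer fixture the variation
under random rigid motions is ~1 Å² per residue, far below every
threshold used.

# Region sets and bound references

The packaged configuration (`inst/extdata/p53n_regions.yaml`) defines
Phe19's three χ₁ regions (A = trans well, containing the MDM2-bound
χ₁ = 177°; B = gauche−; C = gauche+) and six χ₁ × χ₂ rectangles for
Trp23 (the three χ₁ wells split by the sign of χ₂, with region 1
containing the MDM2-bound reference). These bounds are configuration,
not code: they are this package's estimate of the state partition, and
users should replace them when they have better ones. Intervals are
half-open [lo, hi) and evaluated in label order, so boundary frames
classify deterministically.

Bound-reference matching uses a circular distance of at most 40° on each
defined χ angle. The 40° default is an operationalisation — roughly the
half-width of a rotamer well — and is echoed in every output. Among the
packaged references only Phe19/MDM2 (χ₁ 177°, χ₂ 71°) is a measured
literature value; the others are synthetic stand-ins placed inside the
rotamer well each complex selects, flagged `synthetic: true` in the
file, because the real complex structures cannot be bundled here.
Region populations keep unassigned frames in the denominator (the
partition plus "unassigned" sums to 1); bound-reference populations are
over all non-missing frames. Both denominators are printed.

# Helix assignment and unfolding times

Full DSSP needs an electrostatic hydrogen-bond energy model; this
analysis only needs helix/not-helix over a nine-residue window, so a
simplified rule is used and documented as such: a residue is helical if
it sits in a run of ≥ 4 consecutive residues inside the α basin
(φ ∈ [−100°, −30°], ψ ∈ [−80°, −5°]) **or** is spanned by an
O(i)→N(i+4) distance < 3.5 Å. On ideal helix and extended fixtures this
rule gives helix fractions of exactly 1 and 0.

The unfolding time τᵤ is the first frame where backbone RMSD over the
helical window exceeds 2.5 Å **and** helix fraction falls below 0.25,
sustained for ≥ 10 frames (defaults; all three are mandatory, echoed
parameters). The dwell requirement debounces single-frame excursions.
τᵤ is monotone non-decreasing in the RMSD threshold and non-increasing
in the helix-fraction threshold; the tests assert this on every fixture.
Helix-state statistics exclude a 1 ns equilibration prefix by default.
These numeric criteria are a declared operationalisation: reference
analyses of this system combined secondary structure, RMSD and visual
inspection without publishing thresholds, so exact per-trajectory
reproduction of published unfolding times from new simulations is not
claimed. The packaged reference table reproduces the published group
summary (MDM2-started helices 24.5 ± 11.8 ns; Taz2-started
5.2 ± 3.1 ns) by plain arithmetic.

# The synthetic generator

The generator emulates the *statistical* structure of unbound-peptide MD
trajectories — nothing more. Frames are built with an ideal-geometry
internal-coordinate constructor (fixed Engh--Huber-like bond lengths and
angles, NeRF placement), so every requested φ/ψ/χ is reproduced exactly
(< 10⁻⁶ °) on readback at zero noise; with 0.1 Å Gaussian coordinate
noise the documented angle tolerance is 25°. Defaults are the study
conditions: helix state at φ/ψ = −57°/−47°, coil drawn from the
PPII/β region (φ ∈ [−150°, −70°], ψ ∈ [110°, 170°]), angular jitter
±10° around state centres, backbone two-state switching with geometric
dwell times (matching the run-length logic the transition counter
debounces). Side-chain states are redrawn independently every frame by
default (`rotamerDwellFrames = 1`), which makes frame counts binomial —
the assumption behind every standard-error formula in the population
module; larger dwells are available for kinetics-style tests. A
two-residue coupling option draws pair categories (both/only-A/only-B/
neither) so a target joint population (e.g. the 51 % A1 state of
Phe19+Trp23) is hit exactly in expectation while marginals stay at their
targets.

What the generator does **not** emulate: sterics, energetics, solvent,
realistic transition pathways, or backbone--side-chain coupling beyond
the two-state switch. Passing tests therefore demonstrate that the
analysis stages measure what they claim on data with known truth — not
that real MD ensembles behave like the generator.

The synthetic cage complex surrounds chosen side chains with a rigid
shell of dummy carbon atoms (radius 4 Å, 40 points per atom, pruned near
non-pocket residues). It buries side chains essentially completely
(< 5 Å²) while leaving other residues exposed. Because a cage cannot
bury a residue's backbone without occluding its covalent neighbours,
cage-based anchor tests use the classifier's side-chain measure; the
default for real complexes remains total per-residue SASA.

# Numerical choices and degenerate inputs

* Collinear torsion quadruples raise an error in the scalar API and
  yield `NA` in the vectorised series extractor (the frame is then
  excluded, with the exclusion counted).
* Superposition requires ≥ 3 points with non-degenerate spread;
  reflections are rejected by forcing det = +1.
* PDB I/O is fixed-column v3 through `bio3d`, with a line-level pre-scan
  so malformed ATOM records fail with their line number; altloc other
  than blank/'A' is dropped; coordinates beyond the field width refuse
  to write. Round trips preserve coordinates to the format's 10⁻³ Å.
* Problem sizes in the shipped tests and acceptance script — 2000-frame
  state series, 100–250 replicate batches, 100-frame coordinate
  ensembles, 20 cage fixtures — were chosen so the statistical bounds
  (3 binomial SE, 3–4σ oracle agreement) are sharp while a full run
  stays in the low minutes on a single core.

# Known limitations

* The helix rule is a proxy, not DSSP; it is validated on ideal
  geometry, and borderline 3₁₀/turn conformations may classify
  differently than DSSP would.
* Radii are element-based; NACCESS itself differentiates some atom
  types (e.g. aromatic vs aliphatic carbon). Absolute SASA values can
  differ from NACCESS by a few per cent; differences and thresholds
  (Δ SASA, 15 Å²) are robust to this.
* Region bounds and most bound references for p53N are estimates, and
  the matching tolerance (40°) is a declared substitute for an
  unpublished criterion; conclusions about a specific complex should
  re-measure the references from its structure.
* The generator's coil state is a fixed basin, not a realistic
  disordered ensemble; disordered-state SASA from generated coils is
  only qualitatively (helix < coil) meaningful.
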