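# IDPAnchor

Anchor-residue and side-chain rotamer analysis for intrinsically
disordered peptide ensembles.

## The problem

Intrinsically disordered proteins (IDPs) bind their partners without a
fixed tertiary structure of their own. At the interface, a few *anchor
residues* insert deeply into the partner's binding groove: they are
solvent-exposed in the unbound chain and become essentially fully buried
(solvent-accessible surface area, SASA ≤ 15 Å²) upon binding. The p53
transactivation peptide **p53N** (Glu17–Asn29, `ETFSDLWKLLPEN`) is the
canonical example: it anchors into MDM2 through Phe19, Trp23 and Leu26,
but into Taz2 through Leu22 — the same helix rotated to present a
different face.

The question this package addresses quantitatively: how often does the
*unbound* conformational ensemble of such a peptide already sample the
bound-like side-chain rotamers of its anchor residues, and how does that
depend on whether the transient helix is formed? `IDPAnchor` provides
every analysis stage needed for that workflow, plus a synthetic ensemble
generator with exact ground truth so the whole pipeline is testable
without running molecular dynamics:

* **SASA** — a deterministic Shrake–Rupley engine (Fibonacci point
  lattice, NACCESS-style element radii, probe 1.4 Å) with per-residue
  profiles, complex-minus-partner "unbound" references, and the
  two-sided anchor classification rule (bound ≤ 15 Å² and unbound
  ≥ 30 Å²).
* **Geometry** — torsion angles in the IUPAC convention
  (χ₁ = N–Cα–Cβ–Cγ, χ₂ = Cα–Cβ–Cγ–Cδ₁), Kabsch least-squares
  superposition, per-frame backbone RMSD series.
* **Rotamer states** — circular χ₁ (or χ₁ × χ₂) region sets, bound-like
  conformation matching by circular distance, population estimates with
  binomial errors, joint two-residue matrices with exact marginals,
  debounced transition counting, comparison against a packaged
  rotamer-library reference.
* **Helix dynamics** — simplified helix assignment (α-basin φ/ψ runs or
  the O(i)→N(i+4) hydrogen-bond proxy), unfolding-time detection with a
  sustained two-criterion rule, and helix/disordered state partitioning.
* **Synthetic ensembles** — an ideal-geometry peptide builder (every
  requested φ/ψ/χ reproduced exactly on readback) driving a two-state
  ensemble generator with controllable rotamer populations, dwell times,
  pairwise coupling and coordinate noise.

## Worked example

Build the MDM2-bound-like p53N conformer, bury the three MDM2 anchor
side chains in a synthetic cage receptor, and classify anchors:

```r
library(IDPAnchor)

pep <- buildPeptide(backbone = "helix", chi = list(`19` = c(177, 71)))
chiAngles(pep, 19)
#> chi1 chi2
#>  177   71

cx      <- buildSyntheticComplex(pep, c(19, 23, 26))
bound   <- subset(residueSASA(cx), chain == "A")
unbound <- unboundSASAFromComplex(cx, "A")
rep     <- classifyAnchors(bound, unbound, measure = "sideChain")
anchorResidues(rep)
#> [1] 19 23 26
```

The report's top rows (Å²):

```
resno resname sasaBound sasaUnbound isAnchor
   19     PHE      0.00      137.03     TRUE
   23     TRP      0.00       78.33     TRUE
   26     LEU      0.00       71.24     TRUE
   22     LEU     54.17       82.72    FALSE
```

Phe19, Trp23 and Leu26 lose essentially all side-chain surface on
binding while every other residue stays exposed — exactly the
constructed pocket. Summarising the packaged reference trajectory table
reproduces the headline unfolding statistics:

```r
tab <- referenceUnfoldingTimes()
summarizeUnfolding(tab$unfoldingTimeNs, tab$group)
#>        group  n nUnfolded meanNs      sdNs
#> 1 MDM2-helix 10        10   24.5 11.759157
#> 2 Taz2-helix  5         5    5.2  3.114482
#> 3 disordered  5         0     NA        NA
```

The shell entry point wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/idpanchor.R", package="IDPAnchor"))') \
    simulate --seed 1 --frames 100 --out ens.pdb
```

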