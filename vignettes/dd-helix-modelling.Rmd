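---
title: "Modelling death-domain helical oligomers with ddhelix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling death-domain helical oligomers with ddhelix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Death domains (DDs) are ~90-residue six-helix bundles that assemble into
layered, single-start helical oligomers. The myddosome — the signalling
scaffold of the TLR/IL-1 pathway — stacks a MyD88 DD layer, an IRAK-4 DD
layer and an IRAK DD layer in a left-handed helix. Each subunit touches its
neighbours through three canonical interaction surfaces: a type I interface
with the subunit one position away in helix index, and type II interfaces
with the subunits three and four positions away (one full helical turn,
since the lattice runs at roughly 3.7 subunits per turn). Each interface
pairs an `a` face of one subunit (looking up the helix, toward lower
indices) with a `b` face of its partner.

For the inhibitory kinase IRAK-M, the question is whether its DD layer can
extend this scaffold downward into a homo-octamer: a first IRAK-M tetramer
bound under IRAK-4 through the type IIa face pivoted by Trp74, lateral
tetramerisation through the type Ia face pivoted by Lys60 (with Asp33 the
candidate acidic partner on the neighbouring subunit), and a second tetramer
recruited under the first through the type IIb face pivoted by Arg97 (with
Tyr105), reaching Asp19 of the subunit four positions below. `ddhelix`
rebuilds that modelling chain as a tested pipeline: template-guided
placement, re-anchoring, clash relief, interface analysis, a per-residue
energy decomposition, and an in-silico mutation scan.

## The procedure

1. **Threading stand-in** (`thread_query()`). The query DD model is built
   by copying a homologous template backbone and substituting side chains
   per the query sequence. At aligned positions with identical residues all
   template atoms are copied; at substitutions the backbone (N, CA, C, O,
   CB) is copied and the side chain beyond CB is rebuilt from ideal internal
   coordinates in the extended rotamer. This is deliberately *not* a
   homology model — it is a reproducible geometric stand-in, and is labelled
   as such in its provenance.
2. **Superposition** (`kabsch()`, `superpose_homolog()`). Correspondence
   between homologous chains comes from a global Needleman–Wunsch alignment
   (BLOSUM62, affine gaps open 10 / extend 1); the optimal proper rotation
   is the closed-form SVD solution with the determinant correction, so a
   reflection is never returned. Superposition uses CA atoms only: it is
   fold-level and robust to side-chain differences. No outlier trimming is
   performed, which keeps results deterministic.
3. **Extension and re-anchoring** (`build_extended_layer()`, `reanchor()`).
   One query copy is placed on every subunit of the template's two IRAK
   layers (eight targets in the 6:4:4 architecture). A single rigid
   transform — the joint Kabsch fit of the first four copies onto the
   bottom template layer — then shifts the whole octamer one layer down, so
   the second tetramer extends below the template. The final model keeps
   the template's top two layers (6 + 4) plus the eight query copies at
   helix indices 11–18.
4. **Clash relief** (`detect_clashes()`, `relieve()`). Rigid-body placement
   leaves side-chain bumps. Heavy-atom van der Waals overlaps (Bondi radii;
   reporting threshold 0.4 Å) are relieved by a greedy per-residue
   chi-dihedral grid search (30° steps, worst residue first) that accepts
   only strict reductions of the total overlap. The backbone never moves.
   This is a deterministic debumping pass, not a rotamer-library repack,
   and it makes no claim of reaching the global packing optimum.
5. **Interface analysis** (`contact_map()`, `face_offsets()`,
   `per_residue_energy()`). Contacts are residue pairs from different
   subunits with minimum heavy-atom distance within 4.5 Å. Face statistics
   report, for each pivot residue of each query copy, the helix-index
   offsets of its contact partners and of its nearest partner (the nearest
   partner is reported even beyond the cutoff, so sparse interfaces still
   yield a defined offset). Energies use a simplified single-conformation
   pair potential (below) decomposed per residue.
6. **Mutation scan** (`apply_mutation()`, `delta_score()`,
   `mutation_scan()`). Point mutations of the studied panel (W74A, R97Q,
   K60E, Y105A, F18A, D19N, L20A, P21A, P22A, A23S, Q78x) are applied to
   all eight query copies simultaneously — the biological mutant is
   homotypic — followed by local clash relief of the mutated side chains.
   Score changes are reported per interface class, at rank/sign level only.

## The simplified potential

The per-residue decomposition in the original analysis ran explicit-solvent
molecular dynamics with an MM/GBSA end-state treatment. That is out of
scope at desk scale; `ddhelix` substitutes a documented single-conformation
pair potential over inter-subunit heavy-atom pairs within 10 Å:

$$E_{ij} = \frac{332.0636\, q_i q_j}{\varepsilon(r)\, r}
  + \epsilon_{ij}\left[\left(\frac{r^{min}_{ij}}{r}\right)^{12}
  - 2\left(\frac{r^{min}_{ij}}{r}\right)^{6}\right],
  \qquad \varepsilon(r) = 4r$$

with unit formal charges on the basic/acidic side-chain tips (Lys NZ +1;
Arg NH1/NH2 +0.5 each; Asp OD1/OD2 and Glu OE1/OE2 −0.5 each), everything
else neutral, and element-wise Lennard-Jones parameters. The full pair
energy is credited to both residues of a pair, so summing the per-residue
terms of all subunits gives exactly twice the total pair energy — an
identity the test suite asserts. Units are kcal/mol-scale but arbitrary:
the outputs support ranking and sign arguments, not binding free energies.

Per residue label, the value reported is the **mean of the four lowest
per-copy energies** across the eight query copies (with fewer than four
copies, the mean of all, flagged). The four-of-eight reading — aggregation
across subunit copies rather than across trajectory snapshots — is the
package's interpretation; with eight copies it averages the favourable half
of the distribution and suppresses copies at the helix ends that lack one
of their partners.

## The synthetic fixture

`make_lattice()` generates the study geometry without any external
structure: copies of a synthetic marker domain placed by an exact screw
generator in a 6:4:4 layered, left-handed helix. Defaults (all in
`lattice_spec()`):

| parameter | default | meaning |
|---|---|---|
| twist | −98° | left-handed, ≈3.67 subunits/turn, between 3 and 4 so that both n±3 and n±4 neighbours pack against a subunit |
| rise | 11.75 Å | axial advance per subunit |
| radius | 17 Å | helix axis to subunit centre |
| layers | 6:4:4 | MyD88-, IRAK-4-, IRAK-2-like layer sizes |
| noise_sd | 0 | optional Gaussian coordinate noise |

The marker domain (`make_marker_domain()`) is a three-helix bundle —
a reduced synthetic stand-in for the six-helix DD fold, *not* a model of
any real protein — numbered 15..105 and poly-alanine except for marker
residues at the face-pivot positions (Lys60, Trp74, Arg97, Tyr105, Asp19,
Asp33, Trp52, Arg56, Gln64 and the IIa surround). Helix placements, their
spins about their own axes, one tangential tilt of the first helix and the
loop routing were chosen, once, so that the assembled lattice reproduces
the myddosome offset regime: subunits touch at index offsets {1, 3, 4} and
not 2; the Ia pivot's nearest partner is the subunit one up; the IIa
pivot's nearest partner is three or four up; the nearest acidic IIb partner
(Asp19) of Arg97 sits four below. With these defaults the type II
interfaces carry moderate side-chain bumps — as a raw rigid-body
superposition model should, which is what the debumping stage is for.

What the fixture does *not* emulate: real DD sequence diversity, side-chain
rotamer diversity, the curvature and imperfect screw symmetry of real
myddosome lattices, and any physical salt-bridge geometry at the Ia
interface (the charge-flip property of K60E is therefore tested on a
constructed two-subunit salt-bridge toy, not on the lattice). Passing tests
demonstrate the correctness of the machinery on idealised geometry, not the
biological accuracy of any particular octamer model.

## Numerical choices

- **Screw convention.** The decomposition picks the axis direction so the
  rise is non-negative; then negative twist with positive advance is a
  left-handed helix. Twist lives in (−180°, 180°]; pure translations report
  twist 0 with the axis along the translation; the identity is flagged.
  The axis point is the minimum-norm solution of `(I − R) p = t⊥`.
- **Lattice estimation.** The generator is the Kabsch transform between
  consecutive subunits averaged over all consecutive pairs (rotation mean
  projected back onto SO(3) by SVD), which is robust to local deviations
  and deterministic.
- **Clash exclusions.** Pairs whose separation is fixed by covalent
  geometry are never scored: bonded, 1-3 *and 1-4* neighbours within a
  residue and across the peptide link (plus the proline ring CD). At ideal
  geometry, 1-4 pairs such as O(i)–CB(i) sit near 2.7 Å and would otherwise
  flag every well-formed peptide as self-clashing at the 0.4 Å threshold.
- **Neighbour search.** Cell-list grids (via `data.table` grouping), never
  all-pairs, for both clash detection and the energy cutoff.
- **Determinism.** Relief ties are broken by chain/residue order; the
  pipeline seed is recorded in every manifest; two runs with the same
  configuration produce byte-identical outputs.
- **Side-chain geometry.** Side chains are built from a Z-matrix of ideal
  bond lengths/angles with chi defaults of 180°. Aromatic rings are built
  atom-by-atom and close only approximately; the proline ring CD–N closure
  is not enforced. This is adequate for threading, debumping and
  rank-level scoring, and is one reason no kcal/mol accuracy is claimed.
- **Problem sizes.** The shipped analyses run the full 18-subunit assembly
  (~10,500 heavy atoms); property tests use 2–3 subunit toys and 10-point
  Kabsch instances with 1,000-rotation brute-force oracles.

## Worked example

```r
library(ddhelix)

lat <- make_lattice()                     # synthetic 6:4:4 template
dom <- make_marker_domain()               # query DD stand-in
oct <- build_octamer(dom, lat$structure, lat$manifest)
assembly_table(oct)                       # 6 MyD88 + 4 IRAK4 + 8 QUERY

cm <- contact_map(oct)
table(abs(cm$offset))                     # contacts only at |dn| = 1, 3, 4

faces <- dd_faces()
fo <- face_offsets(oct, faces$Ia)
subset(fo, kind == "nearest")             # Lys60 partners: offset -1

en <- per_residue_energy(oct)
head(rank_residues(en))                   # Trp74 ranks most favourable
```

## Known limitations

- The threading stand-in inherits the template backbone exactly; loops or
  insertions of a real query are omitted, not modelled.
- The potential has no solvation, entropy or polarisation; mutation deltas
  are comparable only in sign and rank.
- The greedy debumping cannot repair backbone-level interpenetration and
  may stop at a local minimum (it reports non-convergence rather than
  failing).
- Type III DD interfaces are never assigned: offsets outside {1, 3, 4}
  report "unclassified" rather than a guessed label.
- The real-template path (an external myddosome PDB plus a real query
  sequence) exercises the same code but its results depend on that input's
  quality; everything asserted by the test suite uses the synthetic
  fixture.
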