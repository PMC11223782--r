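---
title: "Interface pockets, descriptors and the pocketome tree: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface pockets, descriptors and the pocketome tree: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`pocketome` characterizes cavities at protein–protein and protein–ligand
interfaces and organizes them into a similarity graph. The pipeline is:

1. **Structure intake and quality filtering.** PDB/mmCIF files are parsed
   (coordinates via `bio3d`; header metadata and DBREF accessions from the
   raw records). Only NMR, X-ray and cryo-EM structures are considered.
   X-ray structures must have resolution ≤ 3.5 Å and an R-free − R-factor
   gap ≤ 0.07; cryo-EM structures resolution ≤ 3.0 Å and FSC ≤ 0.143; NMR
   entries carry no comparable numeric metric and pass the metric checks.
   All bounds are inclusive, and a missing required metric fails closed:
   with thousands of candidate structures it is cheaper to lose an entry
   with incomplete annotation than to admit an unverifiable one.
2. **Complex selection.** Heterodimers are exactly two polymer chains with
   distinct entity accessions, each with more than three residues (a
   residue counts when at least one heavy atom is resolved). Protein–ligand
   complexes need a non-water, non-polymer residue with at least 8 heavy
   atoms, all from {H, C, N, O, S, P, F, Cl, Br, I}. The size and element
   defaults follow common drug-likeness practice and are configuration
   keys, not structural constants.
3. **Interaction patch.** The epitope is the set of atoms of one partner
   within 6.0 Å (inclusive, all atoms, hydrogens included when present) of
   the other. Structures with alternate-location indicators on any patch
   atom are excluded; alternate locations elsewhere are harmless.
4. **Negative-image cavity detection.** A rectilinear grid is laid over the
   partner-side patch atoms (the partner protein for heterodimers, the
   ligand for PL complexes), expanded by a margin. Grid points clashing
   with the pocket-bearing protein are removed; the remainder are scored
   for buriedness by ray casting against protein heavy-atom spheres; free,
   sufficiently buried points are clustered by 26-connectivity, small
   clusters dropped, and each surviving probe typed by complementarity to
   its nearest protein atom.
5. **Retention and classification.** A pocket is kept when at least 4
   probes lie within 1.0 Å of a partner atom; this removes non-orthosteric
   (HD) and non-liganded (PL) cavities. PL pockets are classified against
   the associated heterodimer after a Kabsch superposition on the shared
   chain's Cα atoms (paired by author residue numbering): with k = number
   of HD-pocket probes within 1.0 Å of a ligand heavy atom, the site is
   orthosteric when k ≥ 4 and allosteric (PLA) otherwise; orthosteric
   sites are competitive (PLOC) when the superposed ligand comes within
   1.0 Å of an epitope atom, else non-competitive (PLONC).
6. **Descriptors.** Each retained pocket gets a fixed, ordered vector of
   109 values: 89 lattice descriptors, 10 amalgamated ratios, 10 geometric
   shape indices (below).
7. **Similarity.** Descriptor columns that are non-zero in strictly more
   than 95% of the pooled pocket sample are kept, standardized to zero
   mean and unit variance, and pairwise Euclidean distances d~ij~ computed.
   The Pocket Similarity Index is the Gaussian kernel
   PSI~ij~ = exp(−d~ij~² / 2σ²), with σ the standard deviation of the
   distances over all unordered pairs; PSI ∈ (0, 1], 1 iff two pockets have
   identical (post-pruning, standardized) descriptors.
8. **Pocketome tree.** An exact minimum spanning tree over the complete
   distance graph, annotated with raw volume, exposure, hydrophobicity,
   aromaticity, asphericity, class and family columns for coloring, and
   exported as JSON, GraphML or an edge table.

Interface hot spots are handled by an independent module: per-residue
free-energy changes (kcal/mol, e.g. from an alanine scan) are labelled
CRITICAL at ΔΔG ≥ 1.5, WARM in [0.5, 1.5), NONE below. The lower bound of
the warm band is taken as inclusive and 1.5 belongs to CRITICAL, so the
bands partition the axis.

# Cavity parameters

All values live in `default_config()$cavity` and are deliberate choices —
the negative-image concept fixes none of them:

| parameter | default | meaning |
|---|---|---|
| `spacing` | 1.5 Å | lattice step; pocket volume is count × spacing³ |
| `margin` | 4.0 Å | box expansion around the seed region |
| `clash_distance` | 2.5 Å | protein heavy-atom exclusion radius |
| `n_rays` | 120 | fixed Fibonacci-sphere directions per point |
| `ray_length` | 8.0 Å | maximum ray travel |
| `atom_radius` | 1.8 Å | blocking sphere radius (≈ carbon van der Waals) |
| `min_buriedness` | 55 | blocked-ray count to keep a point (≈ 46% occlusion) |
| `min_probes` | 10 | smallest cluster reported as a pocket |
| `probe_range` | 4.0 Å | nearest-atom search range for probe typing |

The 1.5 Å spacing balances volume resolution against grid size; 2.5 Å is
just above a typical heavy-atom van der Waals contact, so probes sit in
genuinely open space; 55/120 keeps points that are about half enclosed,
which admits groove-shaped interface pockets while rejecting points over
flat surface; 10 probes ≈ 34 Å³, below which a "pocket" is noise at this
resolution.

The grid origin is the expanded bounding-box minimum corner of the seed
atoms. Because the origin is derived from the input coordinates, the whole
detection is translation-equivariant; it is **not** rotation-equivariant
(the lattice is axis-aligned), which is the usual trade-off for
grid-based cavity detection. Determinism: the ray direction table is a
pure function of `n_rays`, cluster membership comes from integer lattice
adjacency, pockets are ordered by descending probe count with ties broken
by smallest linear grid index, and probe-type ties break by smaller
distance then atom serial.

## Probe typing

Protein heavy atoms carry a pharmacophoric role from a fixed
residue/atom-name table (precedence charged > donor/acceptor > aromatic >
hydrophobic; hydroxyl oxygens are treated as donors; His ring nitrogens as
ND1-donor/NE2-acceptor). The probe takes the complementary type: donors
induce `HB_ACCEPTOR` probes, acceptors `HB_DONOR`, carboxylate oxygens
`DONOR_POS`, protonated nitrogens `ACCEPTOR_NEG`, aromatic ring carbons
`AROMATIC`, other carbon/sulfur `HYDROPHOBIC`; probes with no typed atom
within `probe_range` are `DUMMY`.

# The 109 descriptors

* **89 lattice descriptors**: total volume (Å³), then for each of 8
  categories (the 7 probe types plus total-polar = donor + acceptor +
  charged) the overall probe count and the counts in 10 right-closed
  deciles of normalized buriedness (buriedness / `n_rays`):
  1 + 8 + 8×10 = 89. Only the total of 89 is externally fixed; this
  volume-plus-pharmacophore-by-buriedness layout is the package's
  reconstruction of that count and is documented here as its registry.
* **10 amalgamated ratios**: per-category probe fractions (hydrophobic,
  aromatic, donor, acceptor, positive, negative, polar, dummy), exposure
  (fraction of probes in the lowest three buriedness deciles) and mean
  normalized buriedness; all in [0, 1].
* **10 geometric indices** from the probe cloud with unit masses: radius
  of gyration √(λ₁+λ₂+λ₃) from the gyration spectrum λ₁ ≤ λ₂ ≤ λ₃;
  asphericity ((λ₃−λ₂)² + (λ₂−λ₁)² + (λ₁−λ₃)²) / (2(λ₁+λ₂+λ₃)²);
  spherocity 3λ₁/(λ₁+λ₂+λ₃); from the inertia moments I₁ ≤ I₂ ≤ I₃:
  eccentricity √(1 − I₁/I₃), inertial shape factor I₂/(I₁I₃), the three
  moments themselves, and NPR1 = I₁/I₃, NPR2 = I₂/I₃.

Degenerate conventions: a single probe has Rg = 0, asphericity 0,
spherocity 1, eccentricity 0 and NPR1 = NPR2 = 1; a perfectly collinear
cloud (I₁ = 0) takes inertial shape factor 0 rather than a division by
zero. These conventions keep the vector finite and are exercised in the
unit tests.

# Numerical choices in the similarity stage

* **Strictly greater than 95%** non-zero: a column with exactly 95% of
  values non-zero in a 100-pocket sample is dropped. The boundary is
  tested explicitly.
* **Population standard deviation** (divisor n) both for column scaling
  and for σ. With thousands of pockets the sample/population distinction
  is immaterial, but a single convention keeps results reproducible; the
  alternative is exposed via `sd_type = "sample"`.
* σ is computed over the n(n−1)/2 unordered pairs, excluding the zero
  diagonal. PSI of a pocket with itself is defined as 1.
* Pruning operates on the pooled HD + PL sample by default (both sets
  travel through one matrix); per-subset pruning is available by calling
  `prune_descriptors()` on a subset matrix.
* Constant columns cannot be standardized and are dropped with a warning
  rather than silently producing NaN.

# The pocketome tree

The tree is the exact minimum spanning tree (Kruskal over the complete
graph), not an approximate LSH-forest construction: at the scale this
package targets, exactness is affordable and reproducible. Edge weights
are the distances d (PSI travels along as an edge attribute); since the
kernel is strictly decreasing, minimizing total distance and maximizing
total PSI select the same edge set, a property covered by a test.
Tie-breaking is deterministic: candidate edges are sorted by weight, then
lexicographically by (smaller id, larger id). Node annotations are the
*raw* descriptor values, not the standardized ones, so colors remain
interpretable (volume in Å³, fractions in [0, 1]).

# What the synthetic fixtures emulate

`make_groove_complex()` builds a C-shaped wall of 24 glycine residues
whose atoms tile a 240°-arc tube (radius 5.5 Å, open face up) with either
a 9-residue peptide or a 12-heavy-atom organic-like ligand seated on the
tube axis — a minimal analogue of a groove-and-helix interface such as
MDM2/p53. By construction the complex passes heterodimer/PL selection, has
a dense 6 Å interaction patch, and contains exactly one concave
interface cavity whose negative image survives the buriedness and
retention filters at default parameters (the test suite asserts this, so
any parameter change that breaks the guarantee fails loudly).
`make_flat_chain()` is the negative control: a patch with no enclosure and
therefore no pocket. Quality headers, ΔΔG tables and descriptor matrices
with exact zero fractions and duplicated rows are generated the same way,
all as pure functions of their parameters and seed.

What fixtures do **not** emulate: real side-chain chemistry and rotamers,
crystallographic packing, partial occupancy, sequence-register gaps, or
descriptor distributions of real pocketomes. Green tests demonstrate that
the rules and formulas are implemented as specified and are deterministic;
they do not certify detection performance on experimental structures.

Problem sizes in the shipped tests were chosen so the whole suite runs in
well under a minute of CPU: grids of ~1–2 thousand points per fixture
complex, 10×82 matrices for the kernel checks, complete graphs up to n = 6
against the exhaustive spanning-tree oracle (Prüfer enumeration), and a
four-complex end-to-end run.

# Known limitations

* Pocket detection is grid-based and axis-aligned; probe placements are
  not rotation-equivariant and are not intended to reproduce any licensed
  cavity detector's literal output.
* Chain pairing for superposition matches author residue numbers on the
  shared accession; diverging numbering schemes need renumbered input
  (sequence alignment is out of scope).
* Side-chain completion, protonation and ΔΔG computation are upstream of
  this package: inputs are assumed repaired, and energy tables are
  consumed, not produced.
* mmCIF support covers coordinates and the common quality categories;
  exotic dictionaries may need the sidecar `accessions` argument.
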