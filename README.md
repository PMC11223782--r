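# pocketome

Interface-pocket detection, characterization and similarity graphs for
protein complexes.

Druggable protein–protein interactions are usually attacked through the
pocket where one partner's epitope binds — the orthosteric site — or
through nearby allosteric sites found in liganded monomers. This package
implements the computational chain that turns raw heterodimer (HD) and
protein–ligand (PL) structures into a comparable "pocketome":

* **Quality and selection filters** — experimental-method whitelist (NMR,
  X-ray ≤ 3.5 Å with R-free − R-factor ≤ 0.07, cryo-EM ≤ 3.0 Å with
  FSC ≤ 0.143), heterodimer rule (exactly two polymer chains, distinct
  entity accessions, > 3 residues each), drug-like ligand rule, exclusion
  of alternate locations at the interface.
* **Interaction patch** — all-atom Euclidean 6 Å cutoff between target
  and partner.
* **Negative-image cavities** — unoccupied, partially buried grid points
  near the patch, clustered and typed with complementarity-based
  pharmacophoric probes; retained when ≥ 4 probes lie within 1 Å of a
  partner atom; PL pockets classified as orthosteric-competitive (PLOC),
  orthosteric-non-competitive (PLONC) or allosteric (PLA) against the
  associated heterodimer after shared-chain Kabsch superposition.
* **109 descriptors per pocket** — 89 lattice descriptors (volume +
  probe-category counts by buriedness decile), 10 amalgamated ratios,
  10 geometric shape indices (Rg, asphericity, spherocity, eccentricity,
  inertial shape factor, principal moments, NPRs).
* **Pocket Similarity Index** — after pruning descriptors non-zero in
  > 95% of the sample and z-scaling, pairwise Euclidean distances d_ij
  feed the Gaussian kernel

      PSI_ij = exp( − d_ij² / 2σ² ),   σ = sd of d over all pairs i ≠ j,

  giving similarities in (0, 1] (1 ⇔ identical descriptors).
* **Pocketome tree** — exact minimum spanning tree over the distance
  graph, annotated (volume, exposure, hydrophobicity, aromaticity,
  asphericity, class, family) and exported as JSON / GraphML / TSV.
* **Hot spots** — per-residue ΔΔG tables (FoldX-style or TSV) labelled
  CRITICAL (≥ 1.5 kcal/mol), WARM ([0.5, 1.5)) or NONE.

Deterministic synthetic fixtures (a groove-and-peptide complex emulating
an MDM2/p53-like interface, flat-chain controls, descriptor matrices with
exact zero fractions, quality headers, ΔΔG tables) make every stage
testable without downloading a single structure.

## Worked example

```r
library(pocketome)

td <- tempdir()
paths <- c(hd_groove  = file.path(td, "hd_groove.pdb"),
           hd_groove2 = file.path(td, "hd_groove2.pdb"),
           pl_groove  = file.path(td, "pl_groove.pdb"),
           pl_groove2 = file.path(td, "pl_groove2.pdb"))
make_groove_complex(paths[1], "HD", seed = 1)
make_groove_complex(paths[2], "HD", seed = 2, jitter = 0.1)
make_groove_complex(paths[3], "PL", seed = 3)
make_groove_complex(paths[4], "PL", seed = 4, jitter = 0.1)

s <- read_structure(paths[1])
s
#> structure3d 'hd_groove': 136 atoms, method XRAY
#>   chain A: 24 residues (polymer, FIXA)
#>   chain B: 9 residues (polymer, FIXB)
#>   chain S: 0 residues (het)

ss <- strip_structure(s, "HD")
chain_patch(ss, "A", "B")
#> interface_patch (cutoff 6 A): 87 target atoms / 24 residues;
#>   36 partner atoms / 9 residues

a <- ss$atoms
pk <- detect_pockets(a[a$chain == "A", ], a[a$chain == "B", ],
                     structure_id = s$id)[[1]]
pk
#> pocket 'hd_groove_HD_01' (HD_ORTHOSTERIC): 201 probes, spacing 1.5 A
#>       DUMMY HB_ACCEPTOR    HB_DONOR HYDROPHOBIC
#>          54          45          48          54
```

201 probes at 1.5 Å spacing mean a cavity volume of 201 × 1.5³ ≈ 678 Å³;
the groove's glycine wall offers backbone donors/acceptors and aliphatic
carbons, hence the mixed polar/hydrophobic typing. The descriptor vector
condenses this:

```r
v <- assemble_descriptor_vector(pk)
round(v[c("volume", "frac_hydrophobic", "frac_polar", "exposure",
          "rgyr", "asphericity", "npr1", "npr2")], 4)
#>           volume frac_hydrophobic       frac_polar         exposure
#>         678.3750           0.2687           0.4627           0.0000
#>             rgyr      asphericity             npr1             npr2
#>           6.7182           0.6932           0.1178           0.9935
```

Exposure 0 says every probe is at least 30%-buried; NPR1 ≈ 0.12 with
NPR2 ≈ 0.99 is the rod-like signature of an elongated groove. The full
pipeline over the four complexes:

```r
manifest <- data.frame(path = paths, mode = c("HD", "HD", "PL", "PL"),
                       hd_ref = c("", "", "hd_groove", "hd_groove2"),
                       shared_accession = c("", "", "FIXA", "FIXA"))
report <- run_pipeline(manifest, out_dir = file.path(td, "out"))
str(report[c("n_ok", "n_pockets_retained", "class_counts", "sigma")])
#> List of 4
#>  $ n_ok              : int 4
#>  $ n_pockets_retained: int 4
#>  $ class_counts      :List of 2
#>   ..$ HD  : int 2
#>   ..$ PLOC: int 2
#>  $ sigma             : num 1.87
```

Both ligands sit in their heterodimer's groove and clash with the peptide
epitope, so both PL pockets come out orthosteric-competitive (PLOC).
`out/` now holds `descriptors.csv` (109 columns + metadata), `psi.csv`,
the MOL2 negative images, and the pocketome tree
(`pocketome.json` / `.graphml` / `edges.tsv`), e.g.

```r
read_pocketome_json(file.path(td, "out", "pocketome.json"))$edges
#>             source           target distance          psi
#> 1  pl_groove_PL_01 pl_groove2_PL_01 8.771128 1.676612e-05
#> 2 hd_groove2_AB_01 pl_groove2_PL_01 8.903581 1.199806e-05
#> 3  hd_groove_AB_01 hd_groove2_AB_01 9.021107 8.878581e-06
```

A thin CLI wraps the same functions
(`Rscript inst/cli/pocketome.R run --manifest manifest.tsv --out-dir out`,
plus `interface`, `pockets`, `describe`, `similarity`, `pocketome`,
`hotspots`, `fixtures` subcommands).

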