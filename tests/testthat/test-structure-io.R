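test_that("structures parse with chains, residues, ligands and altlocs", {
  s <- read_structure(hd_fixture())
  ch <- chain_summary(s)
  poly <- ch[ch$polymer, ]
  expect_equal(poly$chain, c("A", "B"))
  expect_equal(poly$n_residues, c(24L, 9L))
  expect_equal(unname(s$accessions[c("A", "B")]), c("FIXA", "FIXB"))

  sp <- read_structure(pl_fixture())
  lig <- pocketome:::find_ligand(sp)
  expect_equal(lig$resname, "LIG")
  expect_equal(lig$heavy_atom_count, 12L)

  # truncated file (no END) still parses; header-only file is a parse error
  lines <- readLines(hd_fixture())
  trunc <- file.path(fixture_dir(), "trunc.pdb")
  writeLines(head(lines, length(lines) - 2L), trunc)
  expect_s3_class(read_structure(trunc), "structure3d")
  empty <- file.path(fixture_dir(), "empty.pdb")
  writeLines(lines[!grepl("^(ATOM|HETATM)", lines)], empty)
  expect_error(read_structure(empty), "parse error")
})

test_that("minimal mmCIF files parse with coordinates and quality fields", {
  cif <- file.path(fixture_dir(), "mini.cif")
  writeLines(c(
    "data_MINI",
    "_exptl.method 'X-RAY DIFFRACTION'",
    "_refine.ls_d_res_high 2.10",
    "_refine.ls_R_factor_R_work 0.180",
    "_refine.ls_R_factor_R_free 0.220",
    "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
             "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_model_num")),
    "ATOM 1 N N . GLY A 1 1 ? 11.104 6.134 -6.504 1.00 0.00 ? 1 GLY A N 1",
    "ATOM 2 C CA . GLY A 1 1 ? 11.639 6.071 -5.147 1.00 0.00 ? 1 GLY A CA 1",
    "ATOM 3 C C . GLY A 1 1 ? 10.729 6.768 -4.123 1.00 0.00 ? 1 GLY A C 1",
    "ATOM 4 O O . GLY A 1 1 ? 9.580 6.342 -4.023 1.00 0.00 ? 1 GLY A O 1"),
    cif)
  s <- read_structure(cif)
  expect_equal(nrow(s$atoms), 4L)
  expect_equal(s$method, "XRAY")
  expect_equal(s$quality$resolution, 2.10)
  expect_equal(s$quality$r_free - s$quality$r_factor, 0.04)
})

test_that("header quality metadata parses; absent fields are NA, never 0", {
  q <- parse_quality(hd_fixture())
  expect_equal(q$method, "XRAY")
  expect_equal(q$resolution, 2.10)
  expect_equal(q$r_free, 0.22)
  expect_equal(q$r_factor, 0.18)
  expect_true(is.na(q$fsc))

  specs <- data.frame(structure_id = c("nmr1", "em1"),
                      method = c("NMR", "CRYOEM"),
                      resolution = c(NA, 2.9),
                      fsc = c(NA, 0.143))
  paths <- make_quality_table(specs, file.path(fixture_dir(), "qt"))
  qn <- parse_quality(paths[1])
  expect_equal(qn$method, "NMR")
  expect_true(is.na(qn$resolution))
  qe <- parse_quality(paths[2])
  expect_equal(qe$method, "CRYOEM")
  expect_equal(qe$resolution, 2.9)
  expect_equal(qe$fsc, 0.143)

  noexp <- file.path(fixture_dir(), "nomethod.pdb")
  writeLines("REMARK   2 RESOLUTION.    2.00 ANGSTROMS.", noexp)
  expect_error(parse_quality(noexp), "metadata error")
})

test_that("quality filter honors method rules and inclusive boundaries", {
  qr <- function(method, res = NA, rf = NA, rw = NA, fsc = NA) {
    passes_quality(quality_record("x", method, res, rf, rw, fsc))
  }
  # X-ray boundary: resolution 3.5 and R-gap 0.07 both pass inclusively
  expect_true(qr("XRAY", 3.5, 0.25, 0.18)$pass)
  expect_false(qr("XRAY", 3.6, 0.25, 0.18)$pass)
  expect_false(qr("XRAY", 3.0, 0.26, 0.18)$pass)   # gap 0.08
  expect_true(qr("XRAY", 3.0, 0.25, 0.18)$pass)    # gap 0.07
  # cryo-EM boundary: 3.0 A and FSC 0.143
  expect_true(qr("CRYOEM", 3.0, fsc = 0.143)$pass)
  expect_false(qr("CRYOEM", 3.0, fsc = 0.144)$pass)
  expect_false(qr("CRYOEM", 3.1, fsc = 0.143)$pass)
  # NMR bypasses metrics; other methods fail; missing metrics fail closed
  expect_true(qr("NMR")$pass)
  expect_false(qr("OTHER", 1.0, 0.2, 0.18)$pass)
  expect_equal(qr("XRAY", 3.0)$reason, "missing metric")
  expect_equal(qr("CRYOEM", 2.0)$reason, "missing metric")
})

test_that("quality filter is monotone: worsening a metric never flips fail to pass", {
  base <- list(
    quality_record("a", "XRAY", 3.5, 0.25, 0.18),
    quality_record("b", "XRAY", 2.0, 0.30, 0.18),
    quality_record("c", "CRYOEM", 3.0, fsc = 0.143),
    quality_record("d", "CRYOEM", 3.5, fsc = 0.10))
  for (q in base) {
    p0 <- passes_quality(q)$pass
    for (delta in c(0.01, 0.1, 1)) {
      worse <- q
      worse$resolution <- q$resolution + delta
      expect_true(!passes_quality(worse)$pass | p0)
      if (!is.na(q$r_free)) {
        worse <- q
        worse$r_free <- q$r_free + delta
        expect_true(!passes_quality(worse)$pass | p0)
      }
      if (!is.na(q$fsc)) {
        worse <- q
        worse$fsc <- q$fsc + delta
        expect_true(!passes_quality(worse)$pass | p0)
      }
    }
  }
})

test_that("heterodimer selection demands two distinct, long-enough chains", {
  ok <- toy_structure(c(A = 24, B = 9), c(A = "P1", B = "P2"))
  expect_true(select_heterodimer(ok)$accepted)

  homo <- toy_structure(c(A = 24, B = 9), c(A = "P1", B = "P1"))
  expect_equal(select_heterodimer(homo)$reason, "homodimer")

  short <- toy_structure(c(A = 24, B = 3), c(A = "P1", B = "P2"))
  expect_equal(select_heterodimer(short)$reason, "too short")
  # strictly more than 3 residues: a 4-residue chain passes
  four <- toy_structure(c(A = 24, B = 4), c(A = "P1", B = "P2"))
  expect_true(select_heterodimer(four)$accepted)

  trimer <- toy_structure(c(A = 10, B = 9, C = 8),
                          c(A = "P1", B = "P2", C = "P3"))
  expect_match(select_heterodimer(trimer)$reason, "not a dimer")

  # invariance under chain reordering
  flipped <- ok
  flipped$atoms <- flipped$atoms[rev(seq_len(nrow(flipped$atoms))), ]
  expect_true(select_heterodimer(flipped)$accepted)
})

test_that("protein-ligand selection enforces size and element rules", {
  ok <- toy_structure(c(A = 20), c(A = "P1"), het_chain = "L",
                      het_elements = rep(c("C", "N", "O"), 4))
  expect_true(select_protein_ligand(ok)$accepted)

  iron <- toy_structure(c(A = 20), c(A = "P1"), het_chain = "L",
                        het_elements = c(rep("C", 11), "Fe"))
  expect_match(select_protein_ligand(iron)$reason, "non-drug-like")

  small <- toy_structure(c(A = 20), c(A = "P1"), het_chain = "L",
                         het_elements = rep("C", 5))
  expect_equal(select_protein_ligand(small)$reason, "too small")
  expect_true(select_protein_ligand(small, min_heavy = 5)$accepted)

  none <- toy_structure(c(A = 20), c(A = "P1"))
  expect_equal(select_protein_ligand(none)$reason, "no ligand")
})

test_that("altloc exclusion applies only to interface atoms", {
  path <- file.path(fixture_dir(), "altloc.pdb")
  make_groove_complex(path, "HD", altloc_at_interface = TRUE)
  s <- strip_structure(read_structure(path), "HD")
  patch <- chain_patch(s, "A", "B")
  expect_true(check_altloc_at_interface(s, patch))

  # altloc far from the interface does not trigger exclusion
  s2 <- strip_structure(read_structure(hd_fixture()), "HD")
  a2 <- s2$atoms
  dist_to_b <- sqrt(pocketome:::min_cross_dist2(
    as.matrix(a2[, c("x", "y", "z")]),
    as.matrix(a2[a2$chain == "B", c("x", "y", "z")])))
  far <- which.max(dist_to_b)
  stopifnot(dist_to_b[far] > 6)
  s2$atoms$altloc[far] <- "B"
  patch2 <- chain_patch(s2, "A", "B")
  expect_false(check_altloc_at_interface(s2, patch2))
})

test_that("stripping removes solvent, is mode-aware and idempotent", {
  s <- read_structure(hd_fixture())
  expect_true(any(s$atoms$water))
  hd <- strip_structure(s, "HD")
  expect_false(any(hd$atoms$het))
  expect_equal(sort(unique(hd$atoms$chain)), c("A", "B"))
  expect_identical(strip_structure(hd, "HD")$atoms, hd$atoms)

  sp <- read_structure(pl_fixture())
  pl <- strip_structure(sp, "PL")
  expect_false(any(pl$atoms$water))
  expect_true(any(pl$atoms$het))                      # ligand retained
  expect_false(any(pl$atoms$resname == "NA"))         # ion dropped
  expect_identical(strip_structure(pl, "PL")$atoms, pl$atoms)
})

test_that("MOL2 round-trip preserves probes exactly", {
  pk <- groove_pocket()
  path <- file.path(fixture_dir(), "pocket.mol2")
  write_mol2(pk, path)
  lines <- readLines(path)
  atom_at <- which(lines == "@<TRIPOS>ATOM")
  expect_equal(length(lines) - atom_at, nrow(pk$probes))
  back <- read_mol2(path)
  expect_equal(nrow(back$probes), nrow(pk$probes))
  expect_equal(back$probes$type, pk$probes$type)
  expect_equal(back$probes$buriedness, pk$probes$buriedness)
  expect_true(max(abs(as.matrix(back$probes[, c("x", "y", "z")]) -
                        as.matrix(pk$probes[, c("x", "y", "z")]))) <= 1e-3)

  empty <- toy_pocket(matrix(numeric(0), ncol = 3))
  expect_error(write_mol2(empty, path), "empty pocket")
})
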