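# Deterministic synthetic fixtures: a C-shaped groove wall with a seated
# peptide (HD) or organic-like ligand (PL), a flat no-cavity control,
# descriptor matrices with controlled zero fractions and duplicate rows,
# quality-metadata headers, and ddG tables. All generators are pure
# functions of their parameters and seed; atom placement is an ideal
# lattice with optional seed-controlled jitter (default 0).

.fixture_wall <- function() {
  # 24 GLY residues in 8 axial stations of 3; each residue contributes 4
  # atoms tiling a 240-degree arc of a tube (radius 5.5 A) open at the top
  radius <- 5.5
  atoms <- NULL
  for (s in 0:7) {
    for (r in 0:2) {
      for (a in 0:3) {
        m <- 4 * r + a
        theta <- (-120 + 240 * m / 11) * pi / 180
        atoms <- rbind(atoms, data.frame(
          name = c("N", "CA", "C", "O")[a + 1],
          element = c("N", "C", "C", "O")[a + 1],
          resname = "GLY", chain = "A", resno = 3 * s + r + 1,
          x = 3 * s + 1.5 * (a %% 2),
          y = radius * sin(theta),
          z = -radius * cos(theta),
          stringsAsFactors = FALSE))
      }
    }
  }
  atoms
}

.fixture_peptide <- function() {
  atoms <- NULL
  for (t in 0:8) {
    x <- 2.5 + 2 * t
    atoms <- rbind(atoms, data.frame(
      name = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      resname = "GLY", chain = "B", resno = t + 1,
      x = x + c(-0.6, 0, 0.6, 0.6),
      y = c(0.45, 0, -0.45, -0.45),
      z = c(0.2, 0, 0.2, 1.4),
      stringsAsFactors = FALSE))
  }
  atoms
}

.fixture_ligand <- function() {
  k <- 0:11
  data.frame(
    name = paste0(c("C", "C", "C", "N", "C", "C", "C", "O", "C", "C", "C",
                    "O"), 1:12),
    element = c("C", "C", "C", "N", "C", "C", "C", "O", "C", "C", "C", "O"),
    resname = "LIG", chain = "L", resno = 1,
    x = 4 + 1.2 * k,
    y = 0.6 * (-1)^k,
    z = 0.3 * (k %% 3 - 1),
    stringsAsFactors = FALSE)
}

expdta_line <- function(method) {
  switch(method,
    XRAY = "EXPDTA    X-RAY DIFFRACTION",
    CRYOEM = "EXPDTA    ELECTRON MICROSCOPY",
    NMR = "EXPDTA    SOLUTION NMR",
    "EXPDTA    NEUTRON DIFFRACTION")
}

quality_header_lines <- function(quality) {
  lines <- expdta_line(quality$method)
  if (!is.null(quality$resolution) && !is.na(quality$resolution)) {
    lines <- c(lines, sprintf(
      "REMARK   2 RESOLUTION.    %5.2f ANGSTROMS.", quality$resolution))
  } else {
    lines <- c(lines, "REMARK   2 RESOLUTION. NOT APPLICABLE.")
  }
  if (!is.null(quality$r_factor) && !is.na(quality$r_factor)) {
    lines <- c(lines, sprintf(
      "REMARK   3   R VALUE            (WORKING SET) : %5.3f",
      quality$r_factor))
  }
  if (!is.null(quality$r_free) && !is.na(quality$r_free)) {
    lines <- c(lines, sprintf(
      "REMARK   3   FREE R VALUE                     : %5.3f",
      quality$r_free))
  }
  if (!is.null(quality$fsc) && !is.na(quality$fsc)) {
    lines <- c(lines, sprintf(
      "REMARK   3   FOURIER SHELL CORRELATION       : %5.3f", quality$fsc))
  }
  lines
}

dbref_line <- function(id, chain, n_res, accession) {
  # accession must land in columns 34-41
  sprintf("DBREF  %-4s %1s %4d %5d  %-6s %-8s %-12s %5d %6d",
          substr(id, 1, 4), chain, 1L, n_res, "UNP", accession, accession,
          1L, n_res)
}

atom_line <- function(serial, name, altloc, resname, chain, resno, x, y, z,
                      element, het = FALSE) {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, name, altloc, resname,
          chain, resno, x, y, z, 1, 0, element)
}

#' Synthetic groove complex fixture
#'
#' Writes a PDB file with chain A, a C-shaped wall of 24 glycine residues
#' forming a concave groove (accession tag `FIXA`). In `"HD"` mode a
#' 9-residue peptide (chain B, accession `FIXB`) sits in the groove with
#' many atom pairs within 6 A; in `"PL"` mode a 12-heavy-atom organic-like
#' ligand (`LIG`) occupies the groove instead. Solvent (3 waters and one
#' sodium ion) is added unless disabled, and REMARK quality fields are
#' configurable. Geometry is an ideal lattice plus optional seed-controlled
#' Gaussian jitter.
#'
#' @param path Output PDB path.
#' @param mode `"HD"` or `"PL"`.
#' @param seed Integer seed controlling the jitter stream.
#' @param jitter Standard deviation (Angstroms) of coordinate jitter
#'   (default 0: fully rigid lattice).
#' @param quality List with `method`, `resolution`, `r_free`, `r_factor`,
#'   `fsc` for the header.
#' @param altloc_at_interface If `TRUE`, one groove-seated atom gets
#'   alternate location indicator `"B"`.
#' @param add_solvent Add waters and an ion (default `TRUE`).
#' @return `path`, invisibly.
#' @export
make_groove_complex <- function(path, mode = c("HD", "PL"), seed = 1L,
                                jitter = 0,
                                quality = list(method = "XRAY",
                                               resolution = 2.1,
                                               r_factor = 0.18,
                                               r_free = 0.22),
                                altloc_at_interface = FALSE,
                                add_solvent = TRUE) {
  mode <- match.arg(mode)
  wall <- .fixture_wall()
  other <- if (mode == "HD") .fixture_peptide() else .fixture_ligand()
  atoms <- rbind(wall, other)
  atoms$het <- atoms$chain == "L"
  if (jitter > 0) {
    set.seed(seed)
    shift <- matrix(stats::rnorm(3 * nrow(atoms), 0, jitter), ncol = 3)
    atoms$x <- atoms$x + shift[, 1]
    atoms$y <- atoms$y + shift[, 2]
    atoms$z <- atoms$z + shift[, 3]
  }
  atoms$x <- round(atoms$x, 3)
  atoms$y <- round(atoms$y, 3)
  atoms$z <- round(atoms$z, 3)
  atoms$altloc <- ""
  if (altloc_at_interface) {
    # first atom of the groove-seated partner is always in the patch
    atoms$altloc[which(atoms$chain != "A")[1]] <- "B"
  }
  id <- toupper(substr(tools::file_path_sans_ext(basename(path)), 1, 4))
  lines <- c(
    sprintf("HEADER    SYNTHETIC GROOVE FIXTURE                01-JAN-20   %s",
            id),
    quality_header_lines(quality),
    dbref_line(id, "A", 24L, "FIXA"),
    if (mode == "HD") dbref_line(id, "B", 9L, "FIXB")
  )
  serial <- 0L
  for (i in seq_len(nrow(atoms))) {
    serial <- serial + 1L
    lines <- c(lines, atom_line(serial, atoms$name[i], atoms$altloc[i],
                                atoms$resname[i], atoms$chain[i],
                                atoms$resno[i], atoms$x[i], atoms$y[i],
                                atoms$z[i], atoms$element[i],
                                het = atoms$het[i]))
  }
  if (add_solvent) {
    sol <- data.frame(
      name = c("O", "O", "O", "NA"),
      element = c("O", "O", "O", "Na"),
      resname = c("HOH", "HOH", "HOH", "NA"),
      resno = c(101L, 102L, 103L, 201L),
      x = c(0, 5, 10, -5), y = c(20, 21, 20, 18), z = c(0, 2, -2, 0))
    for (i in seq_len(nrow(sol))) {
      serial <- serial + 1L
      lines <- c(lines, atom_line(serial, sol$name[i], "", sol$resname[i],
                                  "S", sol$resno[i], sol$x[i], sol$y[i],
                                  sol$z[i], sol$element[i], het = TRUE))
    }
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Flat-chain control fixture (no concavity)
#'
#' A straight glycine chain with a short peptide floating 5 A above it:
#' the interaction patch is non-empty but there is no enclosure, so pocket
#' detection finds nothing at default buriedness.
#'
#' @param path Output PDB path.
#' @param quality Header quality fields as in [make_groove_complex()].
#' @return `path`, invisibly.
#' @export
make_flat_chain <- function(path, quality = list(method = "XRAY",
                                                 resolution = 2.0,
                                                 r_factor = 0.17,
                                                 r_free = 0.21)) {
  atoms <- NULL
  for (t in 0:23) {
    atoms <- rbind(atoms, data.frame(
      name = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      resname = "GLY", chain = "A", resno = t + 1,
      x = 1.5 * t + c(-0.5, 0, 0.5, 0.5),
      y = c(0.4, 0, -0.4, -0.4), z = c(0, 0, 0, 1.2),
      stringsAsFactors = FALSE))
  }
  for (t in 0:3) {
    atoms <- rbind(atoms, data.frame(
      name = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      resname = "GLY", chain = "B", resno = t + 1,
      x = 12 + 2 * t + c(-0.6, 0, 0.6, 0.6),
      y = c(0.45, 0, -0.45, -0.45), z = 5 + c(0.2, 0, 0.2, 1.4),
      stringsAsFactors = FALSE))
  }
  id <- toupper(substr(tools::file_path_sans_ext(basename(path)), 1, 4))
  lines <- c(
    sprintf("HEADER    SYNTHETIC FLAT FIXTURE                  01-JAN-20   %s",
            id),
    quality_header_lines(quality),
    dbref_line(id, "A", 24L, "FIXA"),
    dbref_line(id, "B", 4L, "FIXB"))
  for (i in seq_len(nrow(atoms))) {
    lines <- c(lines, atom_line(i, atoms$name[i], "", atoms$resname[i],
                                atoms$chain[i], atoms$resno[i], atoms$x[i],
                                atoms$y[i], atoms$z[i], atoms$element[i]))
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Synthetic descriptor matrix with controlled structure
#'
#' Generates an n x p positive random matrix, zeroes an exact per-column
#' count of entries to reach the requested zero fractions, and copies exact
#' duplicate rows where requested. Same parameters + seed give a
#' byte-identical file.
#'
#' @param n,p Matrix dimensions (`n >= 2`, `p >= 1`).
#' @param zero_frac Per-column zero fraction, recycled to length `p`; each
#'   must give an integral-feasible count in `0..n` after rounding.
#' @param duplicates List of index pairs `c(i, j)`: row `j` becomes an exact
#'   copy of row `i`. Duplication happens after zeroing, so requested zero
#'   counts are exact only when no duplicates are given.
#' @param seed Integer seed.
#' @param path Optional CSV output path.
#' @param col_names Optional descriptor column names (default `d1..dp`).
#' @return Data frame with `pocket_id` plus `p` descriptor columns;
#'   written to `path` when given.
#' @export
make_descriptor_matrix <- function(n, p = 20L, zero_frac = 0,
                                   duplicates = list(), seed = 1L,
                                   path = NULL, col_names = NULL) {
  stopifnot(n >= 2L, p >= 1L)
  zero_frac <- rep_len(zero_frac, p)
  if (any(zero_frac < 0 | zero_frac > 1)) {
    stop("infeasible zero fraction", call. = FALSE)
  }
  set.seed(seed)
  values <- matrix(round(stats::runif(n * p, 0.5, 2), 6), nrow = n)
  for (j in seq_len(p)) {
    n0 <- as.integer(round(zero_frac[j] * n))
    if (abs(zero_frac[j] * n - n0) > 1e-9) {
      stop("infeasible zero count for column ", j, call. = FALSE)
    }
    if (n0 > 0) values[sample.int(n, n0), j] <- 0
  }
  for (pr in duplicates) {
    stopifnot(length(pr) == 2L, all(pr >= 1), all(pr <= n))
    values[pr[2], ] <- values[pr[1], ]
  }
  if (is.null(col_names)) col_names <- paste0("d", seq_len(p))
  out <- data.frame(pocket_id = sprintf("P%03d", seq_len(n)), values,
                    stringsAsFactors = FALSE)
  names(out) <- c("pocket_id", col_names)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  out
}

#' Materialize quality-record specs as PDB header files
#'
#' Writes one header-only PDB per row of `specs` into `dir` so the header
#' parser and the quality filter can be exercised end to end, including the
#' boundary rows at 3.5 A, 3.0 A, 0.07 and 0.143.
#'
#' @param specs Data frame with `structure_id`, `method` and optional
#'   `resolution`, `r_free`, `r_factor`, `fsc` columns.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths (empty for an empty table).
#' @export
make_quality_table <- function(specs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (nrow(specs) == 0L) return(character(0))
  num_or_na <- function(col, i) {
    if (col %in% names(specs)) specs[[col]][i] else NA_real_
  }
  paths <- character(nrow(specs))
  for (i in seq_len(nrow(specs))) {
    q <- list(method = specs$method[i],
              resolution = num_or_na("resolution", i),
              r_free = num_or_na("r_free", i),
              r_factor = num_or_na("r_factor", i),
              fsc = num_or_na("fsc", i))
    paths[i] <- file.path(dir, paste0(specs$structure_id[i], ".pdb"))
    writeLines(c(
      sprintf("HEADER    SYNTHETIC QUALITY FIXTURE               01-JAN-20   %s",
              toupper(substr(specs$structure_id[i], 1, 4))),
      quality_header_lines(q), "END"), paths[i])
  }
  paths
}

#' Synthetic per-residue ddG table
#'
#' @param path Output path.
#' @param records Optional data frame `chain`, `resnum`, `resname`, `ddg`;
#'   when `NULL`, `n` glycine records with seeded uniform ddG in
#'   (-1, 3) kcal/mol are generated.
#' @param n Number of generated records.
#' @param seed Integer seed.
#' @param dialect `"tsv"` or `"foldx_ala_scan"` output layout.
#' @return `path`, invisibly.
#' @export
make_ddg_table <- function(path, records = NULL, n = 10L, seed = 1L,
                           dialect = c("tsv", "foldx_ala_scan")) {
  dialect <- match.arg(dialect)
  if (is.null(records)) {
    set.seed(seed)
    records <- data.frame(
      chain = "A", resnum = seq_len(n), resname = "GLY",
      ddg = round(stats::runif(n, -1, 3), 3), stringsAsFactors = FALSE)
  }
  if (dialect == "tsv") {
    utils::write.table(records[, c("chain", "resnum", "resname", "ddg")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(sprintf("%s %s %d to ALA energy change is %g",
                       records$resname, records$chain, records$resnum,
                       records$ddg), path)
  }
  invisible(path)
}
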