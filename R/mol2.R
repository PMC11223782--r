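# SYBYL MOL2 export of pocket negative images. One @<TRIPOS>ATOM record per
# probe; the probe pharmacophore type is encoded in the atom name and mapped
# to a SYBYL atom type; the buriedness count is stored in the charge column
# so the file round-trips losslessly.

.probe_mol2 <- data.frame(
  type = c("HYDROPHOBIC", "AROMATIC", "HB_ACCEPTOR", "HB_DONOR",
           "ACCEPTOR_NEG", "DONOR_POS", "DUMMY"),
  name = c("HYD", "ARO", "ACC", "DON", "ANE", "DPO", "DUM"),
  sybyl = c("C.3", "C.ar", "O.3", "N.am", "O.co2", "N.4", "Du"),
  stringsAsFactors = FALSE
)

#' Write a pocket negative image as a SYBYL MOL2 file
#'
#' @param pocket A non-empty `pocket`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mol2 <- function(pocket, path) {
  pr <- pocket$probes
  if (is.null(pr) || nrow(pr) == 0L) {
    stop("empty pocket: refusing to write MOL2", call. = FALSE)
  }
  m <- match(pr$type, .probe_mol2$type)
  lines <- c(
    "@<TRIPOS>MOLECULE",
    pocket$pocket_id,
    sprintf("%5d %5d %5d %5d %5d", nrow(pr), 0L, 1L, 0L, 0L),
    "SMALL",
    "USER_CHARGES",
    "@<TRIPOS>ATOM",
    sprintf("%7d %-8s %9.4f %9.4f %9.4f %-8s %3d %-8s %9.4f",
            seq_len(nrow(pr)), .probe_mol2$name[m],
            pr$x, pr$y, pr$z, .probe_mol2$sybyl[m],
            1L, "POCKET", as.numeric(pr$buriedness))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a pocket MOL2 file written by [write_mol2()]
#'
#' @param path MOL2 file path.
#' @return A `pocket` with probe coordinates, types and buriedness restored
#'   (grid indices are not stored in MOL2 and come back as `NA`).
#' @export
read_mol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mol_at <- which(lines == "@<TRIPOS>MOLECULE")
  atom_at <- which(lines == "@<TRIPOS>ATOM")
  if (!length(mol_at) || !length(atom_at)) {
    stop("not a MOL2 file: ", path, call. = FALSE)
  }
  id <- trimws(lines[mol_at[1] + 1])
  end <- grep("^@<TRIPOS>", lines)
  end <- end[end > atom_at[1]]
  last <- if (length(end)) end[1] - 1L else length(lines)
  rows <- lines[seq(atom_at[1] + 1L, last)]
  rows <- rows[nzchar(trimws(rows))]
  f <- strsplit(trimws(rows), "\\s+")
  probes <- data.frame(
    x = vapply(f, function(v) as.numeric(v[3]), numeric(1)),
    y = vapply(f, function(v) as.numeric(v[4]), numeric(1)),
    z = vapply(f, function(v) as.numeric(v[5]), numeric(1)),
    i = NA_integer_, j = NA_integer_, k = NA_integer_,
    type = .probe_mol2$type[match(vapply(f, `[`, character(1), 2),
                                  .probe_mol2$name)],
    buriedness = vapply(f, function(v) as.numeric(v[9]), numeric(1)),
    stringsAsFactors = FALSE
  )
  new_pocket(pocket_id = id, probes = probes, source = "PL",
             structure_id = id, facing = "", spacing = NA_real_,
             n_rays = NA_integer_)
}
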