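#' Read a macromolecular structure from PDB or mmCIF
#'
#' Parses coordinates (via bio3d), header-level quality metadata and
#' chain-to-accession mappings (DBREF records or mmCIF `_struct_ref`
#' categories) into a single `structure3d` object. Alternate-location
#' indicators and hydrogens, when present in the file, are preserved.
#'
#' @param path Path to a structure file.
#' @param format One of `"auto"` (by file extension), `"pdb"`, `"mmcif"`.
#' @param accessions Optional named character vector mapping chain identifiers
#'   to entity accessions; overrides anything found in the file. Use this as
#'   the sidecar mapping when the file carries no DBREF/struct_ref records.
#' @return A `structure3d` object: list with `id`, `atoms` (data frame with
#'   one row per atom: `serial`, `name`, `altloc`, `resname`, `chain`,
#'   `resno`, `insert`, `x`, `y`, `z`, `element`, `het`, `water`,
#'   `is_heavy`), `accessions`, and `quality` (a `quality_record` or `NULL`
#'   when the header carries no experimental-method record).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           accessions = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      cif = "mmcif", mmcif = "mmcif",
      pdb = "pdb", ent = "pdb",
      "pdb"
    )
  }
  parsed <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    } else {
      # bio3d's cif reader warns about its beta status and optional
      # header categories; neither affects the atom table we consume
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE,
                                       verbose = FALSE))
    },
    error = function(e) {
      stop("parse error in '", path, "' (", format, "): ",
           conditionMessage(e), call. = FALSE)
    }
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop("parse error in '", path, "': no atom records", call. = FALSE)
  }
  element <- at$elesy
  element[is.na(element) | element == ""] <- NA_character_
  # fall back to the first alphabetic character of the atom name
  miss <- is.na(element)
  if (any(miss)) {
    element[miss] <- sub("^[0-9' ]*([A-Za-z]).*$", "\\1",
                         at$elety[miss])
  }
  element <- normalize_element(element)
  resname <- trimws(at$resid)
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resname = resname,
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    element = element,
    het = at$type == "HETATM",
    water = resname %in% c("HOH", "WAT", "DOD", "H2O", "SOL"),
    stringsAsFactors = FALSE
  )
  atoms$is_heavy <- !(atoms$element %in% c("H", "D"))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("parse error in '", path, "': non-finite coordinates", call. = FALSE)
  }
  quality <- tryCatch(parse_quality(path, format = format),
                      error = function(e) NULL)
  acc <- parse_accessions(path, format = format)
  if (!is.null(accessions)) {
    acc[names(accessions)] <- accessions
  }
  out <- list(
    id = tools::file_path_sans_ext(basename(path)),
    atoms = atoms,
    method = if (is.null(quality)) "OTHER" else quality$method,
    quality = quality,
    accessions = acc
  )
  class(out) <- "structure3d"
  out
}

# Canonical element capitalization ("CL" -> "Cl"); unknown strings pass through.
normalize_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}

parse_accessions <- function(path, format) {
  acc <- character(0)
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") {
    db <- grep("^DBREF", lines, value = TRUE)
    for (ln in db) {
      chain <- trimws(substr(ln, 13, 13))
      accession <- trimws(substr(ln, 34, 41))
      if (nzchar(chain) && nzchar(accession)) acc[chain] <- accession
    }
  } else {
    # minimal mmCIF: look for a struct_ref-style loop pairing chain and
    # accession on one row: columns pdbx_strand_id and pdbx_db_accession
    hit <- grep("_struct_ref", lines)
    if (length(hit)) {
      rows <- grep("^[^_#][^ ]*\\s+\\S+", lines[seq(max(hit) + 1,
                   min(max(hit) + 20, length(lines)))], value = TRUE)
      for (ln in rows) {
        f <- strsplit(trimws(ln), "\\s+")[[1]]
        if (length(f) >= 2 && nchar(f[1]) <= 2) acc[f[1]] <- f[2]
      }
    }
  }
  acc
}

#' @export
print.structure3d <- function(x, ...) {
  ch <- chain_summary(x)
  cat("structure3d '", x$id, "': ", nrow(x$atoms), " atoms, method ",
      x$method, "\n", sep = "")
  for (i in seq_len(nrow(ch))) {
    cat("  chain ", ch$chain[i], ": ", ch$n_residues[i], " residues",
        if (ch$polymer[i]) " (polymer" else " (het",
        if (nzchar(ch$accession[i])) paste0(", ", ch$accession[i]) else "",
        ")\n", sep = "")
  }
  invisible(x)
}

#' Summarize chains of a structure
#'
#' Residues are counted as polymer residues with at least one resolved heavy
#' atom. A chain is a polymer chain when it contains at least one ATOM
#' (non-HETATM) record.
#'
#' @param s A `structure3d`.
#' @return Data frame with `chain`, `n_residues`, `polymer`, `accession`.
#' @export
chain_summary <- function(s) {
  a <- s$atoms
  chains <- sort(unique(a$chain))
  out <- data.frame(chain = chains, n_residues = 0L, polymer = FALSE,
                    accession = "", stringsAsFactors = FALSE)
  for (i in seq_along(chains)) {
    ca <- a[a$chain == chains[i], , drop = FALSE]
    out$polymer[i] <- any(!ca$het)
    poly <- ca[!ca$het & ca$is_heavy, , drop = FALSE]
    out$n_residues[i] <- length(unique(paste(poly$resno, poly$insert)))
    acc <- s$accessions[chains[i]]
    out$accession[i] <- if (length(acc) == 1 && !is.na(acc)) acc else ""
  }
  out
}

#' Remove solvent and (in HD mode) heteroatoms
#'
#' Water molecules are removed in both modes. In `"HD"` mode every HETATM
#' residue is removed, leaving the polymer chains of the protein-protein
#' complex. In `"PL"` mode the designated ligand is retained and all other
#' het residues are dropped.
#'
#' @param s A `structure3d`.
#' @param mode `"HD"` (heterodimer) or `"PL"` (protein-ligand).
#' @param ligand_resname In PL mode, residue name of the ligand to keep; by
#'   default the non-water het residue with the most heavy atoms.
#' @return The stripped `structure3d`.
#' @export
strip_structure <- function(s, mode = c("HD", "PL"), ligand_resname = NULL) {
  mode <- match.arg(mode)
  a <- s$atoms
  keep <- !a$water
  if (mode == "HD") {
    keep <- keep & !a$het
  } else {
    lig <- find_ligand(s, resname = ligand_resname)
    keep_het <- rep(FALSE, nrow(a))
    if (!is.null(lig)) keep_het[lig$rows] <- TRUE
    keep <- keep & (!a$het | keep_het)
  }
  s$atoms <- a[keep, , drop = FALSE]
  rownames(s$atoms) <- NULL
  s
}

# Locate the designated ligand: largest non-water het residue by heavy-atom
# count (ties: first by chain/resno). Returns NULL when none present.
find_ligand <- function(s, resname = NULL) {
  a <- s$atoms
  cand <- which(a$het & !a$water)
  if (!is.null(resname)) cand <- cand[a$resname[cand] %in% resname]
  if (!length(cand)) return(NULL)
  key <- paste(a$chain[cand], a$resno[cand], a$insert[cand], a$resname[cand])
  groups <- split(cand, key)
  heavy <- vapply(groups, function(r) sum(a$is_heavy[r]), integer(1))
  ord <- order(-heavy, names(groups))
  rows <- groups[[ord[1]]]
  list(
    resname = a$resname[rows[1]],
    chain = a$chain[rows[1]],
    resno = a$resno[rows[1]],
    atoms = a[rows, , drop = FALSE],
    heavy_atom_count = sum(a$is_heavy[rows]),
    rows = rows
  )
}

#' Heterodimer selection rule
#'
#' Accepts a structure as a heterodimer (HD) complex when, after solvent and
#' heteroatom stripping, exactly two polymer chains remain, their entity
#' accessions are present and distinct, and each chain has more than
#' `min_residues` residues (residues with at least one resolved heavy atom).
#'
#' @param s A `structure3d`.
#' @param min_residues Chains must have strictly more residues than this
#'   (default 3).
#' @return List with `accepted` (logical), `reason` (character, `""` when
#'   accepted), and for accepted complexes `chains`, a two-row chain summary.
#' @export
select_heterodimer <- function(s, min_residues = 3L) {
  ss <- strip_structure(s, "HD")
  ch <- chain_summary(ss)
  ch <- ch[ch$polymer & ch$n_residues > 0, , drop = FALSE]
  if (nrow(ch) != 2L) {
    return(list(accepted = FALSE,
                reason = sprintf("not a dimer (%d polymer chains)", nrow(ch))))
  }
  if (any(!nzchar(ch$accession))) {
    return(list(accepted = FALSE, reason = "missing entity accession"))
  }
  if (ch$accession[1] == ch$accession[2]) {
    return(list(accepted = FALSE, reason = "homodimer"))
  }
  if (any(ch$n_residues <= min_residues)) {
    return(list(accepted = FALSE, reason = "too short"))
  }
  list(accepted = TRUE, reason = "", chains = ch)
}

#' Protein-ligand selection rule
#'
#' Accepts a structure as a PL complex when it carries a ligand (non-polymer,
#' non-water residue) with at least `min_heavy` heavy atoms, all of whose
#' elements fall in the drug-like element set.
#'
#' @param s A `structure3d`.
#' @param min_heavy Minimum ligand heavy-atom count (default 8).
#' @param allowed_elements Permitted ligand elements.
#' @return List with `accepted`, `reason`, and for accepted complexes
#'   `ligand` (residue name, chain, resno, atom table, heavy-atom count).
#' @export
select_protein_ligand <- function(s, min_heavy = 8L,
                                  allowed_elements = drug_like_elements()) {
  lig <- find_ligand(s)
  if (is.null(lig)) {
    return(list(accepted = FALSE, reason = "no ligand"))
  }
  if (lig$heavy_atom_count < min_heavy) {
    return(list(accepted = FALSE, reason = "too small",
                ligand = lig[names(lig) != "rows"]))
  }
  bad <- setdiff(unique(lig$atoms$element), allowed_elements)
  if (length(bad)) {
    return(list(accepted = FALSE,
                reason = sprintf("non-drug-like element (%s)",
                                 paste(bad, collapse = ",")),
                ligand = lig[names(lig) != "rows"]))
  }
  list(accepted = TRUE, reason = "", ligand = lig[names(lig) != "rows"])
}

#' Default drug-like element set
#' @return Character vector of permitted ligand elements.
#' @export
drug_like_elements <- function() {
  c("H", "D", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
}

#' Alternate-location exclusion rule at an interface
#'
#' A structure is excluded when any atom of the interaction patch (either
#' side) carries a non-blank alternate-location indicator.
#'
#' @param s A `structure3d` (unused beyond provenance; the patch carries its
#'   atom rows).
#' @param patch An `interface_patch`.
#' @return `TRUE` when the structure must be excluded.
#' @export
check_altloc_at_interface <- function(s, patch) {
  alt <- c(patch$target_atoms$altloc, patch$partner_atoms$altloc)
  any(nzchar(alt) & alt != " ")
}
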