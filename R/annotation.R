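#' Pocket retention filter
#'
#' A detected pocket is retained when at least `min_contact_probes` of its
#' negative-image probes lie within `contact` Angstroms of a partner atom
#' (partner protein for HD complexes, ligand for PL complexes). This
#' excludes non-orthosteric (HD) and non-liganded (PL) pockets.
#'
#' @param pocket A `pocket`.
#' @param partner_atoms Atom data frame or coordinate matrix of the partner.
#' @param contact Contact distance in Angstroms, inclusive (default 1.0).
#' @param min_contact_probes Minimum qualifying probes (default 4).
#' @return `TRUE` when the pocket is retained.
#' @export
retain_pocket <- function(pocket, partner_atoms, contact = 1.0,
                          min_contact_probes = 4L) {
  k <- contact_probe_count(pocket, partner_atoms, contact)
  k >= min_contact_probes
}

contact_probe_count <- function(pocket, partner_atoms, contact) {
  px <- coord_matrix(pocket$probes)
  ax <- coord_matrix(if (is.data.frame(partner_atoms))
    partner_atoms else partner_atoms)
  if (nrow(px) == 0L || nrow(ax) == 0L) return(0L)
  sum(min_cross_dist2(px, ax) <= contact^2 + 1e-12)
}

#' Rigid superposition on a shared chain
#'
#' Least-squares (Kabsch) superposition of the PL structure onto the HD
#' structure using CA atoms of the chain with the shared entity accession,
#' paired by author residue number and insertion code. The returned
#' transform maps PL coordinates into the HD frame: `x_hd = R x_pl + t`.
#'
#' @param pl,hd `structure3d` objects sharing a chain accession.
#' @param shared_accession The common accession.
#' @return A `superposition`: list with `rotation` (proper 3x3),
#'   `translation`, `rmsd` (Angstroms), `n_pairs`.
#' @export
superpose_shared_chain <- function(pl, hd, shared_accession) {
  pl_ca <- shared_ca(pl, shared_accession)
  hd_ca <- shared_ca(hd, shared_accession)
  key_pl <- paste(pl_ca$resno, pl_ca$insert)
  key_hd <- paste(hd_ca$resno, hd_ca$insert)
  common <- intersect(key_pl, key_hd)
  if (length(common) < 3L) {
    stop("insufficient anchor: fewer than 3 shared CA pairs", call. = FALSE)
  }
  X <- coord_matrix(pl_ca[match(common, key_pl), , drop = FALSE])
  Y <- coord_matrix(hd_ca[match(common, key_hd), , drop = FALSE])
  kb <- kabsch(X, Y)
  fit <- sweep(X, 2, kb$cx) %*% t(kb$rotation)
  fit <- sweep(fit, 2, kb$cy, "+")
  rmsd <- sqrt(mean(rowSums((fit - Y)^2)))
  out <- list(rotation = kb$rotation,
              translation = as.numeric(kb$cy - kb$rotation %*% kb$cx),
              rmsd = rmsd, n_pairs = length(common))
  class(out) <- "superposition"
  out
}

shared_ca <- function(s, accession) {
  chains <- names(s$accessions)[s$accessions == accession]
  if (!length(chains)) {
    stop("no chain with accession '", accession, "' in ", s$id, call. = FALSE)
  }
  a <- s$atoms
  ca <- a[a$chain == chains[1] & !a$het & a$name == "CA" &
            (a$altloc == "" | a$altloc == "A"), , drop = FALSE]
  ca[!duplicated(paste(ca$resno, ca$insert)), , drop = FALSE]
}

# Proper-rotation Kabsch via SVD; det(R) enforced +1.
kabsch <- function(X, Y) {
  cx <- colMeans(X)
  cy <- colMeans(Y)
  H <- crossprod(sweep(X, 2, cx), sweep(Y, 2, cy))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(rotation = R, cx = cx, cy = cy)
}

#' Apply a superposition to coordinates
#'
#' @param coords Coordinate matrix or atom data frame.
#' @param sp A `superposition`.
#' @return Transformed coordinate matrix.
#' @export
apply_superposition <- function(coords, sp) {
  x <- coord_matrix(coords)
  sweep(x %*% t(sp$rotation), 2, sp$translation, "+")
}

#' Classify a liganded pocket against its heterodimer pocket
#'
#' With all geometry in the heterodimer frame (via `superposition`), let `k`
#' be the number of HD-pocket probes with at least one ligand heavy atom
#' within `contact` Angstroms. The ligand site is orthosteric when
#' `k >= min_probes`, otherwise allosteric (`PLA`). Orthosteric sites are
#' competitive (`PLOC`) when any ligand heavy atom lies within
#' `overlap_cutoff` of a superposed partner-epitope atom, else
#' non-competitive (`PLONC`).
#'
#' @param hd_pocket The associated heterodimer `pocket`, or `NULL`.
#' @param ligand_atoms Ligand atom data frame (PL frame; heavy atoms used).
#' @param epitope_atoms Partner-side atoms of the HD interaction patch.
#' @param superposition A `superposition` mapping PL into the HD frame.
#' @param contact Probe-to-ligand contact distance (default 1.0 A).
#' @param min_probes Probe count splitting orthosteric from allosteric
#'   (default 4).
#' @param overlap_cutoff Ligand-to-epitope clash distance deciding
#'   competitive vs non-competitive (default 1.0 A).
#' @return List with `class` (`"PLOC"`, `"PLONC"`, `"PLA"` or
#'   `"unassigned"`), `k`, and `min_epitope_dist` (Angstroms).
#' @export
classify_pl_pocket <- function(hd_pocket, ligand_atoms, epitope_atoms,
                               superposition, contact = 1.0,
                               min_probes = 4L, overlap_cutoff = 1.0) {
  if (is.null(hd_pocket)) {
    warning("no associated heterodimer pocket; classification unassigned")
    return(list(class = "unassigned", k = NA_integer_,
                min_epitope_dist = NA_real_))
  }
  lig <- ligand_atoms
  if (is.data.frame(lig) && "is_heavy" %in% names(lig)) {
    lig <- lig[lig$is_heavy, , drop = FALSE]
  }
  lig_hd <- apply_superposition(lig, superposition)
  probes <- coord_matrix(hd_pocket$probes)
  k <- sum(min_cross_dist2(probes, lig_hd) <= contact^2 + 1e-12)
  epi <- heavy_coords(epitope_atoms)
  min_epi <- if (nrow(epi)) sqrt(min(min_cross_dist2(lig_hd, epi))) else Inf
  cls <- if (k >= min_probes) {
    if (min_epi <= overlap_cutoff) "PLOC" else "PLONC"
  } else {
    "PLA"
  }
  list(class = cls, k = as.integer(k), min_epitope_dist = min_epi)
}
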