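# Protein heavy-atom pharmacophoric roles for probe typing.
#
# Role precedence when one atom could carry several: charged > donor/acceptor
# > aromatic > hydrophobic. Hydroxyl oxygens (Ser OG, Thr OG1, Tyr OH) are
# treated as H-bond donors; His ring nitrogens as donor (ND1) / acceptor
# (NE2) in the neutral tautomer. Backbone N is a donor (except proline),
# backbone O and OXT are acceptors (OXT of the C-terminus is treated as a
# plain acceptor, not charged, since termini are not flagged in the input).

.sidechain_roles <- list(
  ARG = c(NE = "pos", NH1 = "pos", NH2 = "pos"),
  LYS = c(NZ = "pos"),
  ASP = c(OD1 = "neg", OD2 = "neg"),
  GLU = c(OE1 = "neg", OE2 = "neg"),
  SER = c(OG = "donor"),
  THR = c(OG1 = "donor"),
  TYR = c(OH = "donor", CG = "aromatic", CD1 = "aromatic", CD2 = "aromatic",
          CE1 = "aromatic", CE2 = "aromatic", CZ = "aromatic"),
  ASN = c(ND2 = "donor", OD1 = "acceptor"),
  GLN = c(NE2 = "donor", OE1 = "acceptor"),
  HIS = c(ND1 = "donor", NE2 = "acceptor", CG = "aromatic", CD2 = "aromatic",
          CE1 = "aromatic"),
  TRP = c(NE1 = "donor", CG = "aromatic", CD1 = "aromatic", CD2 = "aromatic",
          CE2 = "aromatic", CE3 = "aromatic", CZ2 = "aromatic",
          CZ3 = "aromatic", CH2 = "aromatic"),
  PHE = c(CG = "aromatic", CD1 = "aromatic", CD2 = "aromatic",
          CE1 = "aromatic", CE2 = "aromatic", CZ = "aromatic"),
  MET = c(SD = "acceptor"),
  CYS = c(SG = "donor")
)

#' Pharmacophoric role of a protein heavy atom
#'
#' @param resname Residue names (3-letter codes).
#' @param atom_name Atom names (PDB convention).
#' @param element Element symbols.
#' @return Character vector of roles: `"pos"`, `"neg"`, `"donor"`,
#'   `"acceptor"`, `"aromatic"`, `"hydrophobic"` or `"other"`.
#' @export
atom_role <- function(resname, atom_name, element) {
  n <- length(resname)
  role <- rep("other", n)
  is_c_s <- element %in% c("C", "S")
  role[is_c_s] <- "hydrophobic"
  # backbone
  role[atom_name == "N" & resname != "PRO"] <- "donor"
  role[atom_name %in% c("O", "OXT")] <- "acceptor"
  # side chains
  for (i in seq_len(n)) {
    tab <- .sidechain_roles[[resname[i]]]
    if (!is.null(tab)) {
      r <- tab[atom_name[i]]
      if (!is.na(r)) role[i] <- r
    }
  }
  role
}

# Complementarity: probe type induced by the nearest protein atom's role.
.role_to_probe <- c(
  donor = "HB_ACCEPTOR",
  acceptor = "HB_DONOR",
  neg = "DONOR_POS",
  pos = "ACCEPTOR_NEG",
  aromatic = "AROMATIC",
  hydrophobic = "HYDROPHOBIC",
  other = "DUMMY"
)

#' Fixed probe-type vocabulary
#' @return Character vector of the seven probe types in canonical order.
#' @export
probe_types <- function() {
  c("HYDROPHOBIC", "AROMATIC", "HB_ACCEPTOR", "HB_DONOR",
    "ACCEPTOR_NEG", "DONOR_POS", "DUMMY")
}
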