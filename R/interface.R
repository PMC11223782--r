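#' Interaction patch between two atom selections
#'
#' The interaction patch (epitope) is the set of target atoms within
#' `cutoff` (inclusive) of any partner atom, and symmetrically the partner
#' atoms within `cutoff` of any target atom, by straight Euclidean distance
#' over all atoms (hydrogens included when present, unless `heavy_only`).
#'
#' @param target,partner Atom data frames (as in `structure3d$atoms`); both
#'   must be non-empty.
#' @param cutoff Distance threshold in Angstroms, inclusive (default 6.0).
#' @param heavy_only If `TRUE`, hydrogens are ignored on both sides.
#' @return An `interface_patch`: list with `target_atoms`, `partner_atoms`
#'   (atom-table subsets), `target_residues`, `partner_residues` (unique
#'   chain/resno/insert/resname rows owning the listed atoms) and `cutoff`.
#' @export
interaction_patch <- function(target, partner, cutoff = 6.0,
                              heavy_only = FALSE) {
  if (is.null(target) || nrow(target) == 0L ||
      is.null(partner) || nrow(partner) == 0L) {
    stop("empty selection", call. = FALSE)
  }
  if (heavy_only) {
    target <- target[target$is_heavy, , drop = FALSE]
    partner <- partner[partner$is_heavy, , drop = FALSE]
    if (nrow(target) == 0L || nrow(partner) == 0L) {
      stop("empty selection", call. = FALSE)
    }
  }
  tx <- as.matrix(target[, c("x", "y", "z")])
  px <- as.matrix(partner[, c("x", "y", "z")])
  hit <- cross_within(tx, px, cutoff)
  patch <- list(
    target_atoms = target[hit$a, , drop = FALSE],
    partner_atoms = partner[hit$b, , drop = FALSE],
    target_residues = residue_set(target[hit$a, , drop = FALSE]),
    partner_residues = residue_set(partner[hit$b, , drop = FALSE]),
    cutoff = cutoff
  )
  class(patch) <- "interface_patch"
  patch
}

# Which rows of a are within cutoff of any row of b (and vice versa).
# All-pairs squared distances in column blocks to bound memory; identical
# result set to the brute-force oracle.
cross_within <- function(a, b, cutoff) {
  c2 <- cutoff^2
  a2 <- rowSums(a^2)
  in_a <- rep(FALSE, nrow(a))
  in_b <- rep(FALSE, nrow(b))
  block <- 2048L
  for (s in seq(1L, nrow(b), by = block)) {
    e <- min(s + block - 1L, nrow(b))
    bb <- b[s:e, , drop = FALSE]
    d2 <- outer(a2, rowSums(bb^2), "+") - 2 * tcrossprod(a, bb)
    close <- d2 <= c2 + 1e-9
    in_a <- in_a | rowSums(close) > 0L
    in_b[s:e] <- in_b[s:e] | colSums(close) > 0L
  }
  list(a = which(in_a), b = which(in_b))
}

residue_set <- function(atoms) {
  if (nrow(atoms) == 0L) {
    return(data.frame(chain = character(0), resno = integer(0),
                      insert = character(0), resname = character(0),
                      stringsAsFactors = FALSE))
  }
  u <- !duplicated(paste(atoms$chain, atoms$resno, atoms$insert))
  out <- atoms[u, c("chain", "resno", "insert", "resname"), drop = FALSE]
  out <- out[order(out$chain, out$resno, out$insert), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.interface_patch <- function(x, ...) {
  cat("interface_patch (cutoff ", x$cutoff, " A): ",
      nrow(x$target_atoms), " target atoms / ",
      nrow(x$target_residues), " residues; ",
      nrow(x$partner_atoms), " partner atoms / ",
      nrow(x$partner_residues), " residues\n", sep = "")
  invisible(x)
}

#' Interaction patch between two chains of a complex
#'
#' @param s A `structure3d`.
#' @param target_chain,partner_chain Chain identifiers.
#' @inheritParams interaction_patch
#' @return An `interface_patch`.
#' @export
chain_patch <- function(s, target_chain, partner_chain, cutoff = 6.0,
                        heavy_only = FALSE) {
  a <- s$atoms
  interaction_patch(a[a$chain == target_chain & !a$het, , drop = FALSE],
                    a[a$chain == partner_chain & !a$het, , drop = FALSE],
                    cutoff = cutoff, heavy_only = heavy_only)
}
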