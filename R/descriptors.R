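# Pocket descriptor vector: 89 base lattice descriptors (volume + per-category
# probe counts overall and by buriedness decile), 10 amalgamated ratio
# descriptors, 10 geometric shape descriptors = 109 entries with a globally
# fixed name order.

.descriptor_categories <- function() {
  c(tolower(probe_types()), "polar")
}

#' Fixed 109-entry descriptor name registry
#' @return Character vector of length 109, the global column order.
#' @export
descriptor_names <- function() {
  cats <- .descriptor_categories()
  base <- c("volume",
            paste0("n_", cats),
            unlist(lapply(cats, function(cc) paste0("n_", cc, "_b", 1:10))))
  amal <- c("frac_hydrophobic", "frac_aromatic", "frac_hb_donor",
            "frac_hb_acceptor", "frac_positive", "frac_negative",
            "frac_polar", "frac_dummy", "exposure", "mean_buriedness")
  geo <- c("rgyr", "asphericity", "spherocity", "eccentricity",
           "inertial_shape_factor", "pmi1", "pmi2", "pmi3", "npr1", "npr2")
  c(base, amal, geo)
}

category_counts <- function(pocket) {
  tp <- pocket$probes$type
  counts <- vapply(probe_types(), function(t) sum(tp == t), numeric(1))
  c(counts, polar = unname(counts["HB_ACCEPTOR"] + counts["HB_DONOR"] +
                             counts["ACCEPTOR_NEG"] + counts["DONOR_POS"]))
}

buriedness_bin <- function(pocket) {
  b <- pocket$probes$buriedness / pocket$n_rays
  # right-closed deciles on [0,1]; bin 1 = [0, 0.1]
  pmin(pmax(ceiling(b * 10 - 1e-9), 1L), 10L)
}

#' Base lattice descriptors (89 values)
#'
#' Volume (probe count times spacing cubed, cubic Angstroms), one overall
#' probe count per category (the 7 probe types plus total-polar), and per
#' category the probe counts in 10 right-closed buriedness deciles
#' (buriedness normalized by the ray count).
#'
#' @param pocket A retained `pocket`.
#' @return Named numeric vector of length 89.
#' @export
base_descriptors <- function(pocket) {
  n <- nrow(pocket$probes)
  counts <- category_counts(pocket)
  bins <- buriedness_bin(pocket)
  tp <- pocket$probes$type
  in_cat <- function(cc) {
    if (cc == "polar") {
      tp %in% c("HB_ACCEPTOR", "HB_DONOR", "ACCEPTOR_NEG", "DONOR_POS")
    } else {
      tp == toupper(cc)
    }
  }
  cats <- .descriptor_categories()
  decile <- unlist(lapply(cats, function(cc) {
    vapply(1:10, function(d) sum(bins == d & in_cat(cc)), numeric(1))
  }))
  out <- c(n * pocket$spacing^3, unname(counts), decile)
  names(out) <- descriptor_names()[1:89]
  out
}

#' Amalgamated ratio descriptors (10 values)
#'
#' Fractions of total probes per category (hydrophobic, aromatic, H-bond
#' donor, H-bond acceptor, positive-ionizable, negative-ionizable, polar,
#' dummy), the exposure (fraction of probes in the lowest three buriedness
#' deciles) and the mean normalized buriedness. All lie in [0, 1].
#'
#' @param pocket A retained `pocket` with at least one probe.
#' @return Named numeric vector of length 10.
#' @export
amalgamated_descriptors <- function(pocket) {
  n <- nrow(pocket$probes)
  if (n == 0L) stop("zero probes", call. = FALSE)
  counts <- category_counts(pocket)
  b <- pocket$probes$buriedness / pocket$n_rays
  out <- c(
    counts["HYDROPHOBIC"], counts["AROMATIC"], counts["HB_DONOR"],
    counts["HB_ACCEPTOR"], counts["DONOR_POS"], counts["ACCEPTOR_NEG"],
    counts["polar"], counts["DUMMY"]
  ) / n
  out <- c(out, sum(b <= 0.3 + 1e-12) / n, mean(b))
  names(out) <- descriptor_names()[90:99]
  unname_to(out)
}

unname_to <- function(x) {
  stats::setNames(as.numeric(x), names(x))
}

#' Geometric shape descriptors (10 values)
#'
#' From the gyration-tensor eigenvalues (lambda1 <= lambda2 <= lambda3, in
#' square Angstroms) and the unit-mass principal moments of inertia
#' (I1 <= I2 <= I3) of the probe cloud: radius of gyration, asphericity,
#' spherocity index, molecular eccentricity sqrt(1 - I1/I3), inertial shape
#' factor I2/(I1 I3), the three principal moments, and the normalized
#' ratios NPR1 = I1/I3 and NPR2 = I2/I3.
#'
#' Degenerate conventions: a single probe (I3 = 0) takes eccentricity 0,
#' NPR1 = NPR2 = 1, asphericity 0 and spherocity 1; a collinear cloud
#' (I1 = 0) takes inertial shape factor 0.
#'
#' @param pocket A `pocket` (or anything with `$probes` coordinates).
#' @return Named numeric vector of length 10.
#' @export
geometric_descriptors <- function(pocket) {
  x <- coord_matrix(pocket$probes)
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  S <- crossprod(xc) / n                 # gyration tensor
  lam <- sort(pmax(eigen(S, symmetric = TRUE, only.values = TRUE)$values, 0))
  tr <- sum(lam)
  rgyr <- sqrt(tr)
  if (tr > 0) {
    asph <- ((lam[3] - lam[2])^2 + (lam[2] - lam[1])^2 +
               (lam[1] - lam[3])^2) / (2 * tr^2)
    spher <- 3 * lam[1] / tr
  } else {
    asph <- 0
    spher <- 1
  }
  # unit-mass inertia tensor about the centroid
  I <- diag(sum(rowSums(xc^2)), 3) - crossprod(xc)
  mom <- sort(pmax(eigen(I, symmetric = TRUE, only.values = TRUE)$values, 0))
  if (mom[3] > 0) {
    ecc <- sqrt(max(0, 1 - mom[1] / mom[3]))
    npr1 <- mom[1] / mom[3]
    npr2 <- mom[2] / mom[3]
  } else {
    ecc <- 0
    npr1 <- 1
    npr2 <- 1
  }
  isf <- if (mom[1] > 0) mom[2] / (mom[1] * mom[3]) else 0
  out <- c(rgyr, asph, spher, ecc, isf, mom[1], mom[2], mom[3], npr1, npr2)
  names(out) <- descriptor_names()[100:109]
  out
}

#' Assemble the full 109-entry descriptor vector for a pocket
#'
#' @param pocket A retained `pocket`.
#' @return Named numeric vector of length 109 in the fixed global order.
#' @export
assemble_descriptor_vector <- function(pocket) {
  out <- c(base_descriptors(pocket), amalgamated_descriptors(pocket),
           geometric_descriptors(pocket))
  stopifnot(length(out) == 109L)
  names(out) <- descriptor_names()
  out
}

#' Descriptor matrix over a set of pockets
#'
#' @param pockets List of retained `pocket` objects.
#' @param meta Optional data frame of per-pocket metadata (one row per
#'   pocket, e.g. `structure_id`, `class`, `source`).
#' @return A `descriptor_matrix`: list with `pocket_ids`, `names`, `values`
#'   (n x p matrix), `standardized` flag and `meta`.
#' @export
descriptor_matrix <- function(pockets, meta = NULL) {
  ids <- vapply(pockets, function(p) p$pocket_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate pocket ids", call. = FALSE)
  values <- t(vapply(pockets, assemble_descriptor_vector,
                     numeric(length(descriptor_names()))))
  rownames(values) <- ids
  new_descriptor_matrix(ids, descriptor_names(), values, FALSE, meta)
}

new_descriptor_matrix <- function(ids, names, values, standardized,
                                  meta = NULL) {
  dimnames(values) <- list(ids, names)
  m <- list(pocket_ids = ids, names = names, values = values,
            standardized = standardized, meta = meta)
  class(m) <- "descriptor_matrix"
  m
}

#' Build a descriptor_matrix from a data frame or CSV
#'
#' @param x Data frame with a `pocket_id` column and numeric descriptor
#'   columns, or a path to such a CSV. Non-numeric columns other than
#'   `pocket_id` are carried as metadata.
#' @return A `descriptor_matrix`.
#' @export
as_descriptor_matrix <- function(x) {
  if (is.character(x)) x <- utils::read.csv(x, stringsAsFactors = FALSE)
  stopifnot("pocket_id" %in% names(x))
  num <- vapply(x, is.numeric, logical(1)) & names(x) != "pocket_id"
  values <- as.matrix(x[, num, drop = FALSE])
  meta_cols <- setdiff(names(x)[!num], "pocket_id")
  meta <- if (length(meta_cols)) x[, meta_cols, drop = FALSE] else NULL
  if (anyDuplicated(x$pocket_id)) stop("duplicate pocket ids", call. = FALSE)
  new_descriptor_matrix(x$pocket_id, colnames(values), values, FALSE, meta)
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat("descriptor_matrix: ", length(x$pocket_ids), " pockets x ",
      length(x$names), " descriptors",
      if (x$standardized) " (standardized)", "\n", sep = "")
  invisible(x)
}
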