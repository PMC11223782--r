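#' Prune sparse descriptor columns
#'
#' Keeps a descriptor column only when its fraction of non-zero values is
#' strictly greater than `min_nonzero_frac` of the sample; the order of kept
#' columns is preserved. Pruning on the pooled pocket sample is the
#' production default.
#'
#' @param m A `descriptor_matrix` with at least two rows.
#' @param min_nonzero_frac Strict lower bound on the non-zero fraction
#'   (default 0.95).
#' @return The pruned `descriptor_matrix`, with the dropped names in
#'   attribute `"dropped"`.
#' @export
prune_descriptors <- function(m, min_nonzero_frac = 0.95) {
  n <- nrow(m$values)
  if (n < 2L) stop("need at least 2 pockets", call. = FALSE)
  frac <- colSums(m$values != 0) / n
  keep <- frac > min_nonzero_frac
  if (!any(keep)) stop("all descriptor columns pruned", call. = FALSE)
  out <- new_descriptor_matrix(m$pocket_ids, m$names[keep],
                               m$values[, keep, drop = FALSE],
                               m$standardized, m$meta)
  attr(out, "dropped") <- m$names[!keep]
  out
}

#' Standardize descriptor columns to zero mean and unit variance
#'
#' Column-wise (x - mean)/sd. The scale is the population standard
#' deviation by default (divisor n), switchable to the sample one.
#' Constant columns cannot be scaled and are dropped with a warning.
#'
#' @param m A `descriptor_matrix` (normally pruned first).
#' @param sd_type `"population"` or `"sample"`.
#' @return The standardized `descriptor_matrix`.
#' @export
standardize_descriptors <- function(m, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  v <- m$values
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 pockets", call. = FALSE)
  mu <- colMeans(v)
  ss <- colMeans(sweep(v, 2, mu)^2)
  s <- if (sd_type == "population") sqrt(ss) else sqrt(ss * n / (n - 1))
  const <- s < 1e-12
  if (any(const)) {
    warning("dropping ", sum(const), " constant descriptor column(s): ",
            paste(m$names[const], collapse = ", "))
  }
  keep <- !const
  if (!any(keep)) stop("no non-constant descriptor columns", call. = FALSE)
  z <- sweep(sweep(v[, keep, drop = FALSE], 2, mu[keep]), 2, s[keep], "/")
  new_descriptor_matrix(m$pocket_ids, m$names[keep], z, TRUE, m$meta)
}

#' Pairwise Euclidean distances between pockets
#'
#' Computes the full Euclidean distance matrix over pocket rows together
#' with sigma, the population standard deviation of the n(n-1)/2 distinct
#' pairwise distances, which parameterizes the PSI kernel.
#'
#' @param m A standardized `descriptor_matrix`.
#' @return A `distance_matrix`: list with `d` (n x n symmetric matrix) and
#'   `sigma`.
#' @export
pairwise_distances <- function(m) {
  if (nrow(m$values) < 2L) stop("need at least 2 pockets", call. = FALSE)
  d <- as.matrix(stats::dist(m$values, method = "euclidean"))
  dimnames(d) <- list(m$pocket_ids, m$pocket_ids)
  up <- d[upper.tri(d)]
  sigma <- sqrt(mean((up - mean(up))^2))
  out <- list(d = d, sigma = sigma)
  class(out) <- "distance_matrix"
  out
}

#' Pocket Similarity Index matrix
#'
#' Gaussian-kernel transform of the pairwise distances,
#' `PSI_ij = exp(-d_ij^2 / (2 sigma^2))`, with sigma the standard deviation
#' of the distances over all unordered pairs. PSI lies in (0, 1]; the
#' diagonal is 1 by definition.
#'
#' @param dm A `distance_matrix` with `sigma > 0`.
#' @return A `psi_matrix`: symmetric n x n matrix with attribute `"sigma"`.
#' @export
psi <- function(dm) {
  if (!is.finite(dm$sigma) || dm$sigma <= 0) {
    stop("degenerate pocket set: sigma of pairwise distances is 0",
         call. = FALSE)
  }
  p <- exp(-dm$d^2 / (2 * dm$sigma^2))
  diag(p) <- 1
  attr(p, "sigma") <- dm$sigma
  class(p) <- c("psi_matrix", class(p))
  p
}

#' Nearest pocket neighbors by PSI
#'
#' @param psim A `psi_matrix`.
#' @param pocket_id Query pocket identifier.
#' @param k Number of neighbors, `1 <= k < n`.
#' @return Data frame with `pocket_id` and `psi`, descending by PSI; ties
#'   break lexicographically on pocket id.
#' @export
nearest_neighbors <- function(psim, pocket_id, k) {
  ids <- rownames(psim)
  if (!pocket_id %in% ids) stop("unknown pocket id: ", pocket_id,
                                call. = FALSE)
  stopifnot(k >= 1L, k < length(ids))
  others <- setdiff(ids, pocket_id)
  p <- psim[pocket_id, others]
  ord <- order(-p, others)
  data.frame(pocket_id = others[ord][seq_len(k)],
             psi = unname(p[ord][seq_len(k)]),
             stringsAsFactors = FALSE)
}

#' Full similarity pipeline on a descriptor matrix
#'
#' Convenience composition prune -> standardize -> distances -> PSI.
#'
#' @param m A raw `descriptor_matrix`.
#' @param min_nonzero_frac Pruning threshold (see [prune_descriptors()]).
#' @param sd_type Standardization scale (see [standardize_descriptors()]).
#' @return List with `pruned`, `standardized`, `distances`, `psi`.
#' @export
similarity_pipeline <- function(m, min_nonzero_frac = 0.95,
                                sd_type = "population") {
  pruned <- prune_descriptors(m, min_nonzero_frac)
  std <- standardize_descriptors(pruned, sd_type)
  dm <- pairwise_distances(std)
  list(pruned = pruned, standardized = std, distances = dm, psi = psi(dm))
}
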