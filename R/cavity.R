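#' Deterministic quasi-uniform ray directions
#'
#' Fibonacci-sphere sampling; the direction table is a pure function of `n`,
#' so buriedness values are reproducible across runs and platforms.
#'
#' @param n Number of directions.
#' @return `n x 3` matrix of unit vectors.
#' @export
ray_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Build an axis-aligned grid around a seed region
#'
#' The grid covers the bounding box of the seed atoms expanded by `margin`
#' on every side; the origin is the expanded box's minimum corner, so the
#' lattice is input-derived and translation-equivariant.
#'
#' @param seed_coords Matrix (or atom data frame) of seed-region coordinates;
#'   for interface pockets this is the partner/ligand side of the patch.
#' @param spacing Lattice spacing in Angstroms (> 0).
#' @param margin Box expansion in Angstroms (>= 0).
#' @return A `pocket_grid`: list with `origin`, `spacing`, `dims`.
#' @export
build_grid <- function(seed_coords, spacing = 1.5, margin = 4.0) {
  seed_coords <- coord_matrix(seed_coords)
  if (nrow(seed_coords) == 0L) stop("empty seed region", call. = FALSE)
  stopifnot(spacing > 0, margin >= 0)
  lo <- apply(seed_coords, 2, min) - margin
  hi <- apply(seed_coords, 2, max) + margin
  dims <- pmax(1L, as.integer(floor((hi - lo) / spacing + 1e-9)) + 1L)
  g <- list(origin = unname(lo), spacing = spacing, dims = dims)
  class(g) <- "pocket_grid"
  g
}

coord_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "z")])
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  storage.mode(x) <- "double"
  unname(x)
}

#' All lattice points of a grid
#' @param grid A `pocket_grid`.
#' @return Data frame with integer indices `i`, `j`, `k` (0-based) and
#'   coordinates `x`, `y`, `z`.
#' @export
grid_points <- function(grid) {
  idx <- expand.grid(i = seq_len(grid$dims[1]) - 1L,
                     j = seq_len(grid$dims[2]) - 1L,
                     k = seq_len(grid$dims[3]) - 1L)
  data.frame(idx,
             x = grid$origin[1] + grid$spacing * idx$i,
             y = grid$origin[2] + grid$spacing * idx$j,
             z = grid$origin[3] + grid$spacing * idx$k)
}

#' Occupancy mask of grid points against protein heavy atoms
#'
#' A point is occupied when it lies within `clash_distance` of any heavy
#' atom of the supplied set.
#'
#' @param grid A `pocket_grid`.
#' @param atoms Atom data frame or coordinate matrix (heavy atoms only are
#'   used when an atom data frame is given).
#' @param clash_distance Clash radius in Angstroms.
#' @return Logical vector over `grid_points(grid)` rows.
#' @export
occupancy <- function(grid, atoms, clash_distance = 2.5) {
  pts <- as.matrix(grid_points(grid)[, c("x", "y", "z")])
  ax <- heavy_coords(atoms)
  if (nrow(ax) == 0L) return(rep(FALSE, nrow(pts)))
  min_cross_dist2(pts, ax) <= clash_distance^2 + 1e-12
}

heavy_coords <- function(atoms) {
  if (is.data.frame(atoms) && "is_heavy" %in% names(atoms)) {
    atoms <- atoms[atoms$is_heavy, , drop = FALSE]
  }
  coord_matrix(atoms)
}

# squared distance from each row of a to its nearest row of b
min_cross_dist2 <- function(a, b) {
  a2 <- rowSums(a^2)
  best <- rep(Inf, nrow(a))
  block <- 2048L
  for (s in seq(1L, nrow(b), by = block)) {
    e <- min(s + block - 1L, nrow(b))
    bb <- b[s:e, , drop = FALSE]
    d2 <- outer(a2, rowSums(bb^2), "+") - 2 * tcrossprod(a, bb)
    best <- pmin(best, apply(d2, 1, min))
  }
  pmax(best, 0)
}

#' Buriedness of points by ray casting
#'
#' For each point, counts how many of the `n_rays` fixed directions hit a
#' protein heavy-atom sphere (radius `atom_radius`) within `ray_length`.
#' Points inside an atom sphere score the full ray count.
#'
#' @param points Coordinate matrix (or data frame with x,y,z), one row per
#'   point.
#' @param atoms Atom data frame or coordinate matrix of the enclosing
#'   protein.
#' @param n_rays Number of rays (the buriedness ceiling B).
#' @param ray_length Maximum ray travel in Angstroms.
#' @param atom_radius Blocking sphere radius in Angstroms.
#' @return Integer vector of blocked-ray counts in `0..n_rays`.
#' @export
buriedness <- function(points, atoms, n_rays = 120L, ray_length = 8.0,
                       atom_radius = 1.8) {
  pts <- coord_matrix(points)
  ax <- heavy_coords(atoms)
  U <- ray_directions(n_rays)
  out <- integer(nrow(pts))
  if (nrow(ax) == 0L) return(out)
  r2 <- atom_radius^2
  reach2 <- (ray_length + atom_radius)^2
  for (p in seq_len(nrow(pts))) {
    v <- sweep(ax, 2, pts[p, ])        # atom centers relative to the point
    d2 <- rowSums(v^2)
    near <- d2 <= reach2
    if (!any(near)) next
    v <- v[near, , drop = FALSE]
    d2 <- d2[near]
    if (any(d2 <= r2)) { out[p] <- n_rays; next }
    t <- v %*% t(U)                    # m x B projections on each ray
    perp2 <- d2 - t^2
    hit <- perp2 <= r2 & t > 0
    # entry point of the ray into the sphere must lie within ray_length
    hit[hit] <- (t[hit] - sqrt(r2 - perp2[hit])) <= ray_length
    out[p] <- sum(colSums(hit) > 0L)
  }
  out
}

#' Complementary probe typing for cavity points
#'
#' Each point takes the probe type complementary to its nearest typed
#' protein heavy atom within `range`: donors induce `HB_ACCEPTOR` probes,
#' acceptors `HB_DONOR`, carboxylate oxygens `DONOR_POS`, protonated
#' nitrogens `ACCEPTOR_NEG`, aromatic ring carbons `AROMATIC`, other
#' carbon/sulfur `HYDROPHOBIC`; points with no typed atom in range are
#' `DUMMY`. Ties on distance break by atom serial.
#'
#' @param points Coordinate matrix or data frame.
#' @param atoms Protein atom data frame (heavy atoms used).
#' @param range Interaction range in Angstroms (default 4.0).
#' @return Character vector of probe types.
#' @export
assign_probe_type <- function(points, atoms, range = 4.0) {
  pts <- coord_matrix(points)
  prot <- atoms[atoms$is_heavy, , drop = FALSE]
  prot <- prot[order(prot$serial), , drop = FALSE]
  if (nrow(prot) == 0L) return(rep("DUMMY", nrow(pts)))
  ax <- coord_matrix(prot)
  roles <- atom_role(prot$resname, prot$name, prot$element)
  out <- character(nrow(pts))
  a2 <- rowSums(ax^2)
  for (p in seq_len(nrow(pts))) {
    d2 <- a2 - 2 * drop(ax %*% pts[p, ]) + sum(pts[p, ]^2)
    nearest <- which.min(d2)           # first index wins ties (serial order)
    if (d2[nearest] > range^2 + 1e-12) {
      out[p] <- "DUMMY"
    } else {
      out[p] <- .role_to_probe[[roles[nearest]]]
    }
  }
  out
}

#' Detect interface pockets as grid negative images
#'
#' Pipeline: build a grid around the seed region (the partner or ligand side
#' of the interaction patch), mask points clashing with the protein, keep
#' free points with buriedness at or above `min_buriedness`, cluster
#' surviving points by 26-connectivity, drop clusters smaller than
#' `min_probes`, and type the probes by complementarity. Pockets are ordered
#' by descending probe count (ties by smallest grid index) and the whole
#' procedure is deterministic given inputs and parameters.
#'
#' @param protein_atoms Atom data frame of the protein carrying the pocket
#'   (heavy atoms used for occupancy and buriedness).
#' @param seed_atoms Atom data frame or coordinate matrix seeding the grid.
#' @param params Cavity parameters, see [default_config()] element `cavity`.
#' @param structure_id,source,facing Provenance carried on each pocket;
#'   `source` is `"HD_ORTHOSTERIC"` or `"PL"`.
#' @return List of `pocket` objects; empty list when no cluster survives.
#' @export
detect_pockets <- function(protein_atoms, seed_atoms,
                           params = default_config()$cavity,
                           structure_id = "structure",
                           source = "HD_ORTHOSTERIC", facing = "") {
  grid <- build_grid(seed_atoms, spacing = params$spacing,
                     margin = params$margin)
  pts <- grid_points(grid)
  occ <- occupancy(grid, protein_atoms, params$clash_distance)
  free <- pts[!occ, , drop = FALSE]
  if (nrow(free) == 0L) return(list())
  bur <- buriedness(free, protein_atoms, n_rays = params$n_rays,
                    ray_length = params$ray_length,
                    atom_radius = params$atom_radius)
  keep <- bur >= params$min_buriedness
  free <- free[keep, , drop = FALSE]
  bur <- bur[keep]
  if (nrow(free) == 0L) return(list())
  membership <- cluster26(free, grid$dims)
  sizes <- table(membership)
  good <- as.integer(names(sizes)[sizes >= params$min_probes])
  if (!length(good)) return(list())
  types <- assign_probe_type(free, protein_atoms, range = params$probe_range)
  # order clusters by descending size, ties by smallest linear grid index
  lin <- free$i + grid$dims[1] * (free$j + grid$dims[2] * free$k)
  first <- vapply(good, function(g) min(lin[membership == g]), numeric(1))
  ord <- good[order(-as.integer(sizes[as.character(good)]), first)]
  pockets <- vector("list", length(ord))
  for (n in seq_along(ord)) {
    rows <- which(membership == ord[n])
    rows <- rows[order(lin[rows])]
    probes <- data.frame(free[rows, c("x", "y", "z", "i", "j", "k")],
                         type = types[rows], buriedness = bur[rows],
                         stringsAsFactors = FALSE)
    rownames(probes) <- NULL
    pockets[[n]] <- new_pocket(
      pocket_id = sprintf("%s_%s_%02d", structure_id,
                          if (source == "PL") "PL" else "HD", n),
      probes = probes, source = source, structure_id = structure_id,
      facing = facing, spacing = grid$spacing, n_rays = params$n_rays)
  }
  pockets
}

new_pocket <- function(pocket_id, probes, source, structure_id, facing,
                       spacing, n_rays) {
  p <- list(pocket_id = pocket_id, probes = probes, source = source,
            structure_id = structure_id, facing = facing,
            spacing = spacing, n_rays = n_rays)
  class(p) <- "pocket"
  p
}

#' @export
print.pocket <- function(x, ...) {
  cat("pocket '", x$pocket_id, "' (", x$source, "): ", nrow(x$probes),
      " probes, spacing ", x$spacing, " A\n", sep = "")
  print(table(x$probes$type))
  invisible(x)
}

# 26-connectivity components over integer lattice points.
cluster26 <- function(pts, dims) {
  n <- nrow(pts)
  key <- pts$i + dims[1] * (pts$j + dims[2] * pts$k)
  offsets <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offsets <- offsets[!(offsets$di == 0 & offsets$dj == 0 & offsets$dk == 0), ]
  # half the offsets suffice for an undirected edge list
  offsets <- offsets[offsets$dk > 0 | (offsets$dk == 0 & offsets$dj > 0) |
                       (offsets$dk == 0 & offsets$dj == 0 & offsets$di > 0), ]
  edges <- NULL
  for (o in seq_len(nrow(offsets))) {
    ni <- pts$i + offsets$di[o]
    nj <- pts$j + offsets$dj[o]
    nk <- pts$k + offsets$dk[o]
    ok <- ni >= 0 & nj >= 0 & nk >= 0 &
      ni < dims[1] & nj < dims[2] & nk < dims[3]
    m <- match(ni + dims[1] * (nj + dims[2] * nk), key)
    hit <- ok & !is.na(m)
    if (any(hit)) edges <- rbind(edges, cbind(which(hit), m[hit]))
  }
  if (is.null(edges)) return(seq_len(n))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership
}
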