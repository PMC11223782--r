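test_that("grid construction covers the expanded bounding box", {
  g <- build_grid(matrix(c(0, 0, 0), ncol = 3), spacing = 1.5, margin = 4)
  expect_equal(g$dims, c(6L, 6L, 6L))       # 8 A box side, 1.5 A spacing
  expect_equal(g$origin, c(-4, -4, -4))

  g0 <- build_grid(matrix(c(1, 2, 3), ncol = 3), spacing = 1.5, margin = 0)
  expect_equal(g0$dims, c(1L, 1L, 1L))

  two <- rbind(c(0, 0, 0), c(10, 0, 0))
  g2 <- build_grid(two, spacing = 1.5, margin = 4)
  expect_gt(g2$dims[1], g2$dims[2])
  expect_equal(g2$dims[2], g2$dims[3])

  expect_error(build_grid(matrix(numeric(0), ncol = 3)), "empty seed")
})

test_that("occupancy flags points within the clash distance", {
  g <- build_grid(matrix(c(0, 0, 0), ncol = 3), spacing = 1.0, margin = 3)
  pts <- grid_points(g)
  occ <- occupancy(g, matrix(c(0, 0, 0), ncol = 3), clash_distance = 2.5)
  d <- sqrt(pts$x^2 + pts$y^2 + pts$z^2)
  expect_equal(occ, d <= 2.5 + 1e-12)
  # no atoms in range: whole grid free
  occ2 <- occupancy(g, matrix(c(100, 0, 0), ncol = 3), clash_distance = 2.5)
  expect_false(any(occ2))
})

test_that("buriedness counts blocked rays: full shell, open space, half wall", {
  B <- 120L
  # dense full shell at 4 A blocks every ray
  dirs <- ray_directions(500)
  shell <- 4 * dirs
  expect_equal(buriedness(rbind(c(0, 0, 0)), shell, n_rays = B), B)
  # empty space
  expect_equal(buriedness(rbind(c(0, 0, 0)), matrix(c(50, 50, 50), ncol = 3),
                          n_rays = B), 0L)
  # hemispheric wall below the point blocks about half the rays; the exact
  # count is the number of directions whose ray hits the half shell
  half <- shell[shell[, 3] < 0, , drop = FALSE]
  got <- buriedness(rbind(c(0, 0, 0)), half, n_rays = B)
  # the half shell blocks a bit over half the sphere (atom spheres bulge
  # above the equator); the exact count is pinned by the oracle test below
  expect_gt(got, 0.40 * B)
  expect_lt(got, 0.70 * B)
})

test_that("buriedness agrees with a ray-marching oracle on random scenes", {
  # independent oracle: march each ray in small steps and test proximity
  march_oracle <- function(p, atoms, n_rays, ray_length, r) {
    U <- ray_directions(n_rays)
    steps <- seq(0.02, ray_length, by = 0.02)
    blocked <- 0L
    for (q in seq_len(n_rays)) {
      pts <- sweep(outer(steps, U[q, ]), 2, p, "+")
      d2 <- pocketome:::min_cross_dist2(pts, atoms)
      if (any(d2 <= r^2)) blocked <- blocked + 1L
      }
    blocked
  }
  set.seed(7)
  tried <- 0L
  for (rep in 1:12) {
    atoms <- matrix(runif(3 * 30, -6, 6), ncol = 3)
    p <- runif(3, -2, 2)
    # points inside an atom are fully buried by convention (and excluded
    # by the occupancy mask in the pipeline); the oracle covers free points
    if (min(pocketome:::min_cross_dist2(rbind(p), atoms)) <= 1.9^2) next
    tried <- tried + 1L
    got <- buriedness(rbind(p), atoms, n_rays = 40L, ray_length = 6,
                      atom_radius = 1.8)
    want <- march_oracle(p, atoms, 40L, 6, 1.8)
    expect_equal(got, want)
  }
  expect_gte(tried, 3L)
})

test_that("probe typing follows nearest-atom complementarity", {
  mk <- function(resname, name, element, xyz = c(2, 0, 0)) {
    data.frame(serial = 1L, name = name, altloc = "", resname = resname,
               chain = "A", resno = 1L, insert = "", x = xyz[1], y = xyz[2],
               z = xyz[3], element = element, het = FALSE, water = FALSE,
               is_heavy = TRUE, stringsAsFactors = FALSE)
  }
  origin <- rbind(c(0, 0, 0))
  # backbone carbonyl O is an acceptor -> probe is a donor
  expect_equal(assign_probe_type(origin, mk("GLY", "O", "O")), "HB_DONOR")
  # Phe ring carbon -> aromatic probe
  expect_equal(assign_probe_type(origin, mk("PHE", "CZ", "C")), "AROMATIC")
  # Lys NZ is positively charged -> negative probe
  expect_equal(assign_probe_type(origin, mk("LYS", "NZ", "N")),
               "ACCEPTOR_NEG")
  # Asp carboxylate O -> positive probe
  expect_equal(assign_probe_type(origin, mk("ASP", "OD1", "O")),
               "DONOR_POS")
  # plain aliphatic carbon -> hydrophobic
  expect_equal(assign_probe_type(origin, mk("LEU", "CD1", "C")),
               "HYDROPHOBIC")
  # nothing within range -> DUMMY
  expect_equal(assign_probe_type(origin, mk("GLY", "O", "O", c(10, 0, 0))),
               "DUMMY")
  # tie on distance breaks by atom serial
  two <- rbind(mk("GLY", "O", "O", c(2, 0, 0)), mk("GLY", "N", "N", c(-2, 0, 0)))
  two$serial <- c(1L, 2L)
  expect_equal(assign_probe_type(origin, two), "HB_DONOR")
})

test_that("groove fixture yields a pocket inside the groove; flat chain none", {
  pk <- groove_pocket()
  s <- strip_structure(read_structure(hd_fixture()), "HD")
  a <- s$atoms
  groove <- a[a$chain == "A", ]
  d2 <- pocketome:::min_cross_dist2(
    as.matrix(pk$probes[, c("x", "y", "z")]),
    as.matrix(groove[, c("x", "y", "z")]))
  expect_true(all(d2 <= 36))                 # all probes within 6 A of groove
  expect_gte(nrow(pk$probes), 10)

  flat <- strip_structure(read_structure(flat_fixture()), "HD")
  fa <- flat$atoms
  patch <- chain_patch(flat, "A", "B")
  expect_gt(nrow(patch$partner_atoms), 0)
  expect_length(detect_pockets(fa[fa$chain == "A", ], patch$partner_atoms), 0)
})

test_that("detected probes are free, buried, clustered apart and deterministic", {
  s <- strip_structure(read_structure(hd_fixture()), "HD")
  a <- s$atoms
  patch <- chain_patch(s, "A", "B")
  prot <- a[a$chain == "A", ]
  params <- default_config()$cavity
  pks <- detect_pockets(prot, patch$partner_atoms, params = params)
  for (pk in pks) {
    coords <- as.matrix(pk$probes[, c("x", "y", "z")])
    d2 <- pocketome:::min_cross_dist2(coords, as.matrix(
      prot[prot$is_heavy, c("x", "y", "z")]))
    expect_true(all(d2 > params$clash_distance^2))
    expect_true(all(pk$probes$buriedness >= params$min_buriedness))
  }
  if (length(pks) >= 2) {
    for (i in 1:(length(pks) - 1)) {
      for (j in (i + 1):length(pks)) {
        di <- abs(outer(pks[[i]]$probes$i, pks[[j]]$probes$i, "-"))
        dj <- abs(outer(pks[[i]]$probes$j, pks[[j]]$probes$j, "-"))
        dk <- abs(outer(pks[[i]]$probes$k, pks[[j]]$probes$k, "-"))
        expect_false(any(di <= 1 & dj <= 1 & dk <= 1))
      }
    }
  }
  # determinism
  pks2 <- detect_pockets(prot, patch$partner_atoms, params = params)
  expect_identical(lapply(pks, `[[`, "probes"), lapply(pks2, `[[`, "probes"))
})

test_that("pocket detection is translation-equivariant", {
  s <- strip_structure(read_structure(hd_fixture()), "HD")
  a <- s$atoms
  patch <- chain_patch(s, "A", "B")
  prot <- a[a$chain == "A", ]
  pks <- detect_pockets(prot, patch$partner_atoms)
  t <- c(3.21, -7.77, 0.135)
  shift <- function(df) {
    df$x <- df$x + t[1]; df$y <- df$y + t[2]; df$z <- df$z + t[3]; df
  }
  pks_t <- detect_pockets(shift(prot), shift(patch$partner_atoms))
  expect_equal(length(pks), length(pks_t))
  for (n in seq_along(pks)) {
    expect_equal(as.matrix(pks_t[[n]]$probes[, c("x", "y", "z")]),
                 sweep(as.matrix(pks[[n]]$probes[, c("x", "y", "z")]), 2,
                       t, "+"),
                 tolerance = 1e-9)
    expect_equal(pks_t[[n]]$probes$type, pks[[n]]$probes$type)
  }
})
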