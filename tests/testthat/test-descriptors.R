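test_that("base descriptors: volume, category counts, bin conservation", {
  pk <- toy_pocket(matrix(runif(30), ncol = 3), types = "HYDROPHOBIC",
                   buried = 60, spacing = 1.5)
  b <- base_descriptors(pk)
  expect_length(b, 89L)
  expect_equal(unname(b["volume"]), 10 * 1.5^3)   # 33.75 A^3
  expect_equal(unname(b["n_hydrophobic"]), 10)
  other <- c("n_aromatic", "n_hb_acceptor", "n_hb_donor", "n_acceptor_neg",
             "n_donor_pos", "n_dummy", "n_polar")
  expect_equal(unname(b[other]), rep(0, 7))

  # mixed pocket: decile bins partition each category count
  set.seed(3)
  mixed <- toy_pocket(matrix(runif(60), ncol = 3),
                      types = sample(probe_types(), 20, replace = TRUE),
                      buried = sample(0:120, 20, replace = TRUE))
  bm <- base_descriptors(mixed)
  for (cat in c("hydrophobic", "aromatic", "hb_acceptor", "hb_donor",
                "acceptor_neg", "donor_pos", "dummy", "polar")) {
    bins <- bm[paste0("n_", cat, "_b", 1:10)]
    expect_equal(unname(sum(bins)), unname(bm[paste0("n_", cat)]))
  }
  # typed + dummy counts partition the probe total
  typed <- bm[paste0("n_", tolower(probe_types()))]
  expect_equal(unname(sum(typed)), 20)
})

test_that("amalgamated descriptors are fractions with the stated conventions", {
  hyd <- toy_pocket(matrix(runif(30), ncol = 3), types = "HYDROPHOBIC",
                    buried = 120)
  a <- amalgamated_descriptors(hyd)
  expect_length(a, 10L)
  expect_equal(unname(a["frac_hydrophobic"]), 1)
  expect_equal(unname(a["frac_polar"]), 0)
  expect_equal(unname(a["exposure"]), 0)           # all fully buried
  expect_equal(unname(a["mean_buriedness"]), 1)

  set.seed(5)
  mixed <- toy_pocket(matrix(runif(90), ncol = 3),
                      types = sample(probe_types(), 30, replace = TRUE),
                      buried = sample(0:120, 30, replace = TRUE))
  am <- amalgamated_descriptors(mixed)
  expect_true(all(am >= 0 & am <= 1))
  typed <- am[c("frac_hydrophobic", "frac_aromatic", "frac_hb_donor",
                "frac_hb_acceptor", "frac_positive", "frac_negative",
                "frac_dummy")]
  expect_equal(unname(sum(typed)), 1)

  empty <- toy_pocket(matrix(numeric(0), ncol = 3))
  expect_error(amalgamated_descriptors(empty), "zero probes")
})

test_that("geometric descriptors match closed forms on symmetric clouds", {
  # single probe: all-degenerate conventions
  g1 <- geometric_descriptors(toy_pocket(rbind(c(1, 2, 3))))
  expect_equal(unname(g1["rgyr"]), 0)
  expect_equal(unname(g1["eccentricity"]), 0)
  expect_equal(unname(g1[c("npr1", "npr2")]), c(1, 1))

  # cube corners, side 2: per-coordinate variance 1, so the gyration
  # spectrum is (1,1,1) -> Rg = sqrt(3), asphericity 0, spherocity 1,
  # equal inertia moments -> NPR1 = NPR2 = 1
  cube <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  gc <- geometric_descriptors(toy_pocket(cube))
  expect_equal(unname(gc["rgyr"]), sqrt(3), tolerance = 1e-12)
  expect_equal(unname(gc["asphericity"]), 0, tolerance = 1e-12)
  expect_equal(unname(gc["spherocity"]), 1, tolerance = 1e-12)
  expect_equal(unname(gc[c("npr1", "npr2")]), c(1, 1), tolerance = 1e-12)
  # direct eigen-decomposition oracle for the cube's inertia moments
  xc <- sweep(cube, 2, colMeans(cube))
  I <- diag(sum(rowSums(xc^2)), 3) - crossprod(xc)
  mom <- sort(eigen(I, symmetric = TRUE)$values)
  expect_equal(unname(gc[c("pmi1", "pmi2", "pmi3")]), mom)

  # collinear probes: rod limit
  rod <- cbind(seq(0, 9), 0, 0)
  gr <- geometric_descriptors(toy_pocket(rod))
  expect_equal(unname(gr["npr1"]), 0, tolerance = 1e-12)
  expect_equal(unname(gr["npr2"]), 1, tolerance = 1e-12)
  expect_equal(unname(gr["eccentricity"]), 1, tolerance = 1e-12)
  expect_equal(unname(gr["inertial_shape_factor"]), 0)
})

test_that("geometric descriptors are rigid-invariant and scale correctly", {
  set.seed(9)
  pts <- matrix(rnorm(45), ncol = 3)
  g0 <- geometric_descriptors(toy_pocket(pts))
  # random proper rotation + translation
  qr_R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_R) < 0) qr_R[, 1] <- -qr_R[, 1]
  moved <- sweep(pts %*% t(qr_R), 2, c(10, -4, 2), "+")
  g1 <- geometric_descriptors(toy_pocket(moved))
  expect_equal(g1, g0, tolerance = 1e-6)
  # scaling: Rg linear, PMIs quadratic, dimensionless indices unchanged
  s <- 2.5
  g2 <- geometric_descriptors(toy_pocket(pts * s))
  expect_equal(unname(g2["rgyr"]), unname(s * g0["rgyr"]), tolerance = 1e-9)
  expect_equal(unname(g2[c("pmi1", "pmi2", "pmi3")]),
               unname(s^2 * g0[c("pmi1", "pmi2", "pmi3")]),
               tolerance = 1e-9)
  expect_equal(unname(g2[c("asphericity", "spherocity", "npr1", "npr2",
                           "eccentricity")]),
               unname(g0[c("asphericity", "spherocity", "npr1", "npr2",
                           "eccentricity")]), tolerance = 1e-9)
})

test_that("descriptor vectors have 109 fixed, named, deterministic entries", {
  expect_length(descriptor_names(), 109L)
  pk <- groove_pocket()
  v <- assemble_descriptor_vector(pk)
  expect_length(v, 109L)
  expect_equal(names(v), descriptor_names())
  expect_identical(v, assemble_descriptor_vector(pk))
  expect_true(all(v[grep("^n_", names(v))] >= 0))
  expect_true(v["spherocity"] >= 0 && v["spherocity"] <= 1)
  expect_true(v["asphericity"] >= 0 && v["asphericity"] <= 1)
  expect_true(v["npr1"] >= 0 && v["npr1"] <= v["npr2"] &&
                v["npr2"] <= 1)
})
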