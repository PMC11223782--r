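# Shared fixtures, generated once per test session into a temp dir.

.fixture_env <- new.env(parent = emptyenv())

fixture_dir <- function() {
  if (is.null(.fixture_env$dir)) {
    .fixture_env$dir <- file.path(tempdir(), "pocketome-fixtures")
    dir.create(.fixture_env$dir, showWarnings = FALSE)
  }
  .fixture_env$dir
}

fixture_pdb <- function(name, fun) {
  path <- file.path(fixture_dir(), paste0(name, ".pdb"))
  if (!file.exists(path)) fun(path)
  path
}

hd_fixture <- function() fixture_pdb("hda", function(p)
  make_groove_complex(p, "HD", seed = 1))

pl_fixture <- function() fixture_pdb("pla", function(p)
  make_groove_complex(p, "PL", seed = 3))

flat_fixture <- function() fixture_pdb("flat", function(p)
  make_flat_chain(p))

# Minimal in-memory structure3d for selection-rule tests.
toy_structure <- function(chains, accessions, het_chain = NULL,
                          het_elements = NULL, id = "toy") {
  atoms <- NULL
  serial <- 0L
  for (ci in seq_along(chains)) {
    n_res <- chains[ci]
    ch <- names(chains)[ci]
    for (r in seq_len(n_res)) {
      serial <- serial + 1L
      atoms <- rbind(atoms, data.frame(
        serial = serial, name = "CA", altloc = "", resname = "GLY",
        chain = ch, resno = r, insert = "",
        x = 3 * r + 20 * ci, y = 0, z = 0, element = "C", het = FALSE,
        water = FALSE, is_heavy = TRUE, stringsAsFactors = FALSE))
    }
  }
  if (!is.null(het_chain)) {
    for (e in seq_along(het_elements)) {
      serial <- serial + 1L
      atoms <- rbind(atoms, data.frame(
        serial = serial, name = paste0(het_elements[e], e), altloc = "",
        resname = "LIG", chain = het_chain, resno = 1L, insert = "",
        x = e, y = 5, z = 0, element = het_elements[e], het = TRUE,
        water = FALSE, is_heavy = !het_elements[e] %in% c("H", "D"),
        stringsAsFactors = FALSE))
    }
  }
  s <- list(id = id, atoms = atoms, method = "XRAY", quality = NULL,
            accessions = accessions)
  class(s) <- "structure3d"
  s
}

# Synthetic pocket with chosen probe types/buriedness on a 1.5 A lattice.
toy_pocket <- function(coords, types = "HYDROPHOBIC", buried = 60,
                       spacing = 1.5, n_rays = 120L, id = "toy_pk") {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  probes <- data.frame(
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    i = rep(NA_integer_, n), j = rep(NA_integer_, n),
    k = rep(NA_integer_, n),
    type = rep_len(types, n), buriedness = rep_len(buried, n),
    stringsAsFactors = FALSE)
  p <- list(pocket_id = id, probes = probes, source = "PL",
            structure_id = id, facing = "", spacing = spacing,
            n_rays = n_rays)
  class(p) <- "pocket"
  p
}

# One detected-and-retained groove pocket, computed once and reused.
groove_pocket <- function() {
  if (is.null(.fixture_env$groove_pocket)) {
    s <- read_structure(hd_fixture())
    ss <- strip_structure(s, "HD")
    patch <- chain_patch(ss, "A", "B")
    a <- ss$atoms
    pks <- detect_pockets(a[a$chain == "A", ], patch$partner_atoms,
                          structure_id = s$id)
    stopifnot(length(pks) >= 1)
    .fixture_env$groove_pocket <- pks[[1]]
  }
  .fixture_env$groove_pocket
}

# Cached 4-complex pipeline run shared by pipeline and acceptance tests.
pipeline_fixture <- function() {
  if (is.null(.fixture_env$pipeline)) {
    td <- file.path(fixture_dir(), "pipeline")
    dir.create(td, showWarnings = FALSE)
    paths <- c(
      hd_fixture(),
      fixture_pdb("hdb", function(p)
        make_groove_complex(p, "HD", seed = 2, jitter = 0.1)),
      pl_fixture(),
      fixture_pdb("plb", function(p)
        make_groove_complex(p, "PL", seed = 4, jitter = 0.1)))
    manifest <- data.frame(
      path = paths, mode = c("HD", "HD", "PL", "PL"),
      hd_ref = c("", "", "hda", "hdb"),
      shared_accession = c("", "", "FIXA", "FIXA"),
      family = c("grooveA", "grooveA", "grooveB", "grooveB"),
      stringsAsFactors = FALSE)
    out_dir <- file.path(td, "out")
    report <- run_pipeline(manifest, out_dir = out_dir)
    .fixture_env$pipeline <- list(manifest = manifest, out_dir = out_dir,
                                  report = report)
  }
  .fixture_env$pipeline
}
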