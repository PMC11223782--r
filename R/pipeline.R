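#' Default pipeline configuration
#'
#' All tunables of the pipeline, grouped by stage. Unknown keys passed to
#' [merge_config()] are rejected.
#'
#' @return Nested list of parameters:
#' \describe{
#'   \item{quality}{`resolution_xray_max` (3.5 A), `resolution_cryoem_max`
#'     (3.0 A), `rgap_max` (0.07), `fsc_max` (0.143); all inclusive upper
#'     bounds.}
#'   \item{ligand}{`min_heavy` (8), `allowed_elements` (H,C,N,O,S,P and
#'     halogens).}
#'   \item{interface}{`cutoff` (6.0 A, inclusive), `heavy_only` (FALSE).}
#'   \item{cavity}{`spacing` (1.5 A), `margin` (4.0 A), `clash_distance`
#'     (2.5 A), `n_rays` (120), `ray_length` (8.0 A), `atom_radius`
#'     (1.8 A), `min_buriedness` (55 of 120 rays), `min_probes` (10),
#'     `probe_range` (4.0 A).}
#'   \item{retention}{`contact` (1.0 A), `min_contact_probes` (4).}
#'   \item{classify}{`contact` (1.0 A), `min_probes` (4), `overlap_cutoff`
#'     (1.0 A).}
#'   \item{similarity}{`min_nonzero_frac` (0.95, strict), `sd_type`
#'     (`"population"`).}
#'   \item{hotspots}{`critical_min` (1.5 kcal/mol), `warm_min`
#'     (0.5 kcal/mol).}
#' }
#' @export
default_config <- function() {
  list(
    quality = list(resolution_xray_max = 3.5, resolution_cryoem_max = 3.0,
                   rgap_max = 0.07, fsc_max = 0.143),
    ligand = list(min_heavy = 8L, allowed_elements = drug_like_elements()),
    interface = list(cutoff = 6.0, heavy_only = FALSE),
    cavity = list(spacing = 1.5, margin = 4.0, clash_distance = 2.5,
                  n_rays = 120L, ray_length = 8.0, atom_radius = 1.8,
                  min_buriedness = 55L, min_probes = 10L,
                  probe_range = 4.0),
    retention = list(contact = 1.0, min_contact_probes = 4L),
    classify = list(contact = 1.0, min_probes = 4L, overlap_cutoff = 1.0),
    similarity = list(min_nonzero_frac = 0.95, sd_type = "population"),
    hotspots = list(critical_min = 1.5, warm_min = 0.5)
  )
}

#' Merge user settings into the default configuration
#'
#' @param user Nested list of overrides; unknown groups or keys are an
#'   error.
#' @return The merged configuration list.
#' @export
merge_config <- function(user = list()) {
  config <- default_config()
  for (grp in names(user)) {
    if (!grp %in% names(config)) stop("unknown config group: ", grp,
                                      call. = FALSE)
    for (key in names(user[[grp]])) {
      if (!key %in% names(config[[grp]])) {
        stop("unknown config key: ", grp, ".", key, call. = FALSE)
      }
      config[[grp]][[key]] <- user[[grp]][[key]]
    }
  }
  config
}

process_structure <- function(row, config) {
  rec <- list(id = NA_character_, path = row$path, mode = row$mode,
              status = "ok", reason = "", pockets = list(),
              n_detected = 0L, n_retained = 0L)
  s <- read_structure(row$path)
  rec$id <- s$id
  if (is.null(s$quality)) {
    rec$status <- "rejected"; rec$reason <- "no quality metadata"
    return(rec)
  }
  qc <- passes_quality(s$quality, config$quality)
  if (!qc$pass) {
    rec$status <- "rejected"; rec$reason <- paste0("quality: ", qc$reason)
    return(rec)
  }
  if (row$mode == "HD") {
    sel <- select_heterodimer(s)
    if (!sel$accepted) {
      rec$status <- "rejected"; rec$reason <- paste0("selection: ", sel$reason)
      return(rec)
    }
    ss <- strip_structure(s, "HD")
    chains <- sel$chains$chain
    a <- ss$atoms
    # detect on both partners, treating the other as the ligand in turn
    for (ti in 1:2) {
      tc <- chains[ti]; pc <- chains[3 - ti]
      patch <- chain_patch(ss, tc, pc, cutoff = config$interface$cutoff,
                           heavy_only = config$interface$heavy_only)
      if (nrow(patch$target_atoms) == 0L) next
      if (check_altloc_at_interface(ss, patch)) {
        rec$status <- "rejected"; rec$reason <- "altloc at interface"
        return(rec)
      }
      partner_atoms <- a[a$chain == pc, , drop = FALSE]
      pks <- detect_pockets(a[a$chain == tc, , drop = FALSE],
                            patch$partner_atoms, params = config$cavity,
                            structure_id = s$id, source = "HD_ORTHOSTERIC",
                            facing = pc)
      rec$n_detected <- rec$n_detected + length(pks)
      for (p in pks) {
        p$pocket_id <- sprintf("%s_%s%s_%s", s$id, tc, pc,
                               sub("^.*_", "", p$pocket_id))
        if (retain_pocket(p, partner_atoms,
                          contact = config$retention$contact,
                          min_contact_probes =
                            config$retention$min_contact_probes)) {
          p$class <- "HD"
          rec$pockets <- c(rec$pockets, list(p))
        }
      }
    }
    rec$patch <- chain_patch(ss, chains[1], chains[2],
                             cutoff = config$interface$cutoff)
    rec$structure <- ss
  } else {
    sel <- select_protein_ligand(s, min_heavy = config$ligand$min_heavy,
                                 allowed_elements =
                                   config$ligand$allowed_elements)
    if (!sel$accepted) {
      rec$status <- "rejected"; rec$reason <- paste0("selection: ", sel$reason)
      return(rec)
    }
    ss <- strip_structure(s, "PL", ligand_resname = sel$ligand$resname)
    a <- ss$atoms
    lig_atoms <- a[a$het, , drop = FALSE]
    prot_atoms <- a[!a$het, , drop = FALSE]
    patch <- interaction_patch(prot_atoms, lig_atoms,
                               cutoff = config$interface$cutoff,
                               heavy_only = config$interface$heavy_only)
    if (check_altloc_at_interface(ss, patch)) {
      rec$status <- "rejected"; rec$reason <- "altloc at interface"
      return(rec)
    }
    pks <- detect_pockets(prot_atoms, lig_atoms, params = config$cavity,
                          structure_id = s$id, source = "PL",
                          facing = sel$ligand$resname)
    rec$n_detected <- length(pks)
    for (p in pks) {
      if (retain_pocket(p, lig_atoms, contact = config$retention$contact,
                        min_contact_probes =
                          config$retention$min_contact_probes)) {
        p$class <- "PL"
        rec$pockets <- c(rec$pockets, list(p))
      }
    }
    rec$ligand_atoms <- lig_atoms
    rec$structure <- ss
  }
  rec$n_retained <- length(rec$pockets)
  rec
}

#' Run the full interface-pocketome pipeline
#'
#' Executes quality filter, HD/PL selection, solvent stripping, interface
#' patch, pocket detection, retention filter, PL pocket classification
#' (when a manifest row names its associated HD complex and shared
#' accession), descriptor computation, pooled pruning and standardization,
#' PSI, and the minimum-spanning-tree pocketome, writing per-stage
#' artifacts and a JSON run report with counts at each stage.
#'
#' @param manifest Data frame (or TSV path) with columns `path`, `mode`
#'   (`"HD"` or `"PL"`) and optional `hd_ref` (structure id of the
#'   associated HD complex), `shared_accession`, `family`.
#' @param config Configuration from [default_config()] / [merge_config()].
#' @param out_dir Output directory; created if needed.
#' @return The run report (list), invisibly. Artifacts: `descriptors.csv`,
#'   `psi.csv`, `pocketome.json` / `.graphml` / `edges.tsv`, per-pocket
#'   MOL2 files under `pockets/`, and `report.json`.
#' @export
run_pipeline <- function(manifest, config = default_config(), out_dir) {
  if (is.character(manifest)) {
    manifest <- utils::read.table(manifest, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  }
  stopifnot(all(c("path", "mode") %in% names(manifest)))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  records <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    records[[i]] <- tryCatch(
      process_structure(manifest[i, , drop = FALSE], config),
      error = function(e) list(id = basename(manifest$path[i]),
                               path = manifest$path[i],
                               mode = manifest$mode[i], status = "error",
                               reason = conditionMessage(e),
                               pockets = list(), n_detected = 0L,
                               n_retained = 0L))
  }
  names(records) <- vapply(records, function(r) r$id, character(1))
  # classify PL pockets against their associated HD complex
  if ("hd_ref" %in% names(manifest)) {
    for (i in seq_len(nrow(manifest))) {
      r <- records[[i]]
      ref <- manifest$hd_ref[i]
      if (r$mode != "PL" || r$status != "ok" || is.na(ref) ||
          !nzchar(ref) || !length(r$pockets)) {
        next
      }
      hd <- records[[ref]]
      if (is.null(hd) || hd$status != "ok" || !length(hd$pockets)) next
      sp <- superpose_shared_chain(r$structure, hd$structure,
                                   manifest$shared_accession[i])
      hd_pocket <- hd$pockets[[1]]
      for (jp in seq_along(r$pockets)) {
        cls <- classify_pl_pocket(
          hd_pocket, r$ligand_atoms, hd$patch$partner_atoms, sp,
          contact = config$classify$contact,
          min_probes = config$classify$min_probes,
          overlap_cutoff = config$classify$overlap_cutoff)
        records[[i]]$pockets[[jp]]$class <- cls$class
      }
    }
  }
  pockets <- unlist(lapply(records, function(r) r$pockets),
                    recursive = FALSE)
  report <- list(
    n_structures = nrow(manifest),
    n_ok = sum(vapply(records, function(r) r$status == "ok", logical(1))),
    rejected = lapply(
      Filter(function(r) r$status != "ok", records),
      function(r) list(id = r$id, status = r$status, reason = r$reason)),
    n_pockets_detected = sum(vapply(records, function(r) r$n_detected,
                                    integer(1))),
    n_pockets_retained = length(pockets),
    class_counts = as.list(table(vapply(pockets, function(p) p$class,
                                        character(1)))),
    config = config
  )
  if (length(pockets) >= 2L) {
    meta <- data.frame(
      pocket_id = vapply(pockets, function(p) p$pocket_id, character(1)),
      structure_id = vapply(pockets, function(p) p$structure_id,
                            character(1)),
      source = vapply(pockets, function(p) p$source, character(1)),
      class = vapply(pockets, function(p) p$class, character(1)),
      stringsAsFactors = FALSE)
    if ("family" %in% names(manifest)) {
      meta$family <- manifest$family[match(meta$structure_id,
                                           vapply(records, function(r) r$id,
                                                  character(1)))]
      meta$family[is.na(meta$family)] <- ""
    }
    dm <- descriptor_matrix(pockets, meta = meta)
    desc_df <- data.frame(pocket_id = dm$pocket_ids, meta[, -1, drop = FALSE],
                          dm$values, stringsAsFactors = FALSE,
                          check.names = FALSE)
    utils::write.csv(desc_df, file.path(out_dir, "descriptors.csv"),
                     row.names = FALSE, quote = FALSE)
    pruned <- prune_descriptors(dm, config$similarity$min_nonzero_frac)
    std <- standardize_descriptors(pruned, config$similarity$sd_type)
    distances <- pairwise_distances(std)
    sim <- list(pruned = pruned, standardized = std, distances = distances)
    if (distances$sigma > 0) {
      psim <- psi(distances)
      utils::write.csv(
        data.frame(pocket_id = rownames(psim), unclass(psim),
                   check.names = FALSE),
        file.path(out_dir, "psi.csv"), row.names = FALSE, quote = FALSE)
    } else {
      # a single pair (or all-equidistant set) has no distance spread;
      # the Gaussian kernel is undefined there
      report$note <- "sigma of pairwise distances is 0; PSI not computed"
    }
    tree <- minimum_spanning_tree(sim$distances)
    tree <- annotate_nodes(tree, dm, metadata = meta)
    export_graph(tree, "json", file.path(out_dir, "pocketome.json"))
    export_graph(tree, "graphml", file.path(out_dir, "pocketome.graphml"))
    export_graph(tree, "edge_tsv", file.path(out_dir, "edges.tsv"))
    pocket_dir <- file.path(out_dir, "pockets")
    if (!dir.exists(pocket_dir)) dir.create(pocket_dir)
    for (p in pockets) {
      write_mol2(p, file.path(pocket_dir, paste0(p$pocket_id, ".mol2")))
    }
    report$n_descriptors <- ncol(dm$values)
    report$n_descriptors_kept <- ncol(sim$standardized$values)
    report$sigma <- sim$distances$sigma
    report$mst_total_distance <- sum(tree$edges$distance)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
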