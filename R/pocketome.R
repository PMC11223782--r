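#' Minimum spanning tree over pocket distances
#'
#' Exact MST (Kruskal with union-find) on the complete graph whose edge
#' weights are the descriptor-space distances. Candidate edges are examined
#' in increasing weight, ties broken lexicographically by (smaller id,
#' larger id), so the edge set is deterministic even under weight ties.
#' Because the PSI kernel is strictly decreasing in distance, the same tree
#' minimizes total distance and maximizes total similarity.
#'
#' @param dm A `distance_matrix` (or plain symmetric matrix with dimnames).
#' @param ids Optional node identifiers overriding the matrix dimnames.
#' @return A `pocketome_tree`: list with `nodes` (data frame, one row per
#'   pocket, annotation columns filled by [annotate_nodes()]) and `edges`
#'   (data frame `source`, `target`, `distance`, `psi` when available).
#' @export
minimum_spanning_tree <- function(dm, ids = NULL) {
  d <- if (inherits(dm, "distance_matrix")) dm$d else as.matrix(dm)
  psim <- if (inherits(dm, "distance_matrix") && dm$sigma > 0) {
    exp(-d^2 / (2 * dm$sigma^2))
  } else {
    NULL
  }
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 pockets", call. = FALSE)
  if (is.null(ids)) ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  pair <- which(upper.tri(d), arr.ind = TRUE)
  lo <- pmin(ids[pair[, 1]], ids[pair[, 2]])
  hi <- pmax(ids[pair[, 1]], ids[pair[, 2]])
  w <- d[pair]
  ord <- order(w, lo, hi)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  take <- integer(0)
  for (e in ord) {
    ra <- find(pair[e, 1])
    rb <- find(pair[e, 2])
    if (ra != rb) {
      parent[ra] <- rb
      take <- c(take, e)
      if (length(take) == n - 1L) break
    }
  }
  edges <- data.frame(source = lo[take], target = hi[take],
                      distance = w[take], stringsAsFactors = FALSE)
  if (!is.null(psim)) edges$psi <- psim[pair[take, , drop = FALSE]]
  edges <- edges[order(edges$distance, edges$source, edges$target), ]
  rownames(edges) <- NULL
  tree <- list(nodes = data.frame(pocket_id = sort(ids),
                                  stringsAsFactors = FALSE),
               edges = edges)
  class(tree) <- "pocketome_tree"
  tree
}

#' @export
print.pocketome_tree <- function(x, ...) {
  cat("pocketome_tree: ", nrow(x$nodes), " pockets, ", nrow(x$edges),
      " edges, total distance ", format(sum(x$edges$distance)), "\n",
      sep = "")
  invisible(x)
}

#' Attach annotation columns to pocketome tree nodes
#'
#' Adds the raw (pre-standardization) volume, exposure, hydrophobicity,
#' aromaticity and asphericity descriptor values plus categorical class and
#' family tags for graph coloring.
#'
#' @param tree A `pocketome_tree`.
#' @param descriptors A raw `descriptor_matrix` covering every node.
#' @param metadata Optional data frame with `pocket_id` and any of `class`,
#'   `family`.
#' @return The annotated `pocketome_tree`.
#' @export
annotate_nodes <- function(tree, descriptors, metadata = NULL) {
  ids <- tree$nodes$pocket_id
  at <- match(ids, descriptors$pocket_ids)
  if (anyNA(at)) {
    stop("missing descriptor row for node(s): ",
         paste(ids[is.na(at)], collapse = ", "), call. = FALSE)
  }
  v <- descriptors$values
  pick <- function(col) if (col %in% colnames(v)) v[at, col] else NA_real_
  tree$nodes$volume <- pick("volume")
  tree$nodes$exposure <- pick("exposure")
  tree$nodes$hydrophobicity <- pick("frac_hydrophobic")
  tree$nodes$aromaticity <- pick("frac_aromatic")
  tree$nodes$asphericity <- pick("asphericity")
  tree$nodes$class <- ""
  tree$nodes$family <- ""
  if (!is.null(metadata)) {
    mat <- match(ids, metadata$pocket_id)
    if ("class" %in% names(metadata)) {
      cl <- metadata$class[mat]
      tree$nodes$class <- ifelse(is.na(cl), "", cl)
    }
    if ("family" %in% names(metadata)) {
      fam <- metadata$family[mat]
      tree$nodes$family <- ifelse(is.na(fam), "", fam)
    }
  }
  tree
}

#' Export a pocketome tree
#'
#' `json` round-trips losslessly through [read_pocketome_json()]; `graphml`
#' is schema-valid GraphML with node/edge data keys; `edge_tsv` is a plain
#' `source<TAB>target<TAB>distance` table.
#'
#' @param tree A `pocketome_tree`.
#' @param format `"graphml"`, `"json"` or `"edge_tsv"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_graph <- function(tree, format = c("graphml", "json", "edge_tsv"),
                         path) {
  format <- match.arg(format)
  switch(format,
    json = jsonlite::write_json(
      list(nodes = tree$nodes, edges = tree$edges), path,
      dataframe = "rows", digits = NA, auto_unbox = TRUE),
    edge_tsv = utils::write.table(
      tree$edges[, c("source", "target", "distance")], path,
      sep = "\t", quote = FALSE, row.names = FALSE),
    graphml = write_graphml(tree, path)
  )
  invisible(path)
}

#' Read back a JSON pocketome export
#' @param path File written by `export_graph(..., format = "json")`.
#' @return A `pocketome_tree`.
#' @export
read_pocketome_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tree <- list(nodes = as.data.frame(x$nodes), edges = as.data.frame(x$edges))
  class(tree) <- "pocketome_tree"
  tree
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

write_graphml <- function(tree, path) {
  nodes <- tree$nodes
  edges <- tree$edges
  num_cols <- setdiff(names(nodes)[vapply(nodes, is.numeric, logical(1))],
                      "pocket_id")
  chr_cols <- setdiff(names(nodes), c("pocket_id", num_cols))
  keydefs <- c(
    sprintf('  <key id="%s" for="node" attr.name="%s" attr.type="double"/>',
            num_cols, num_cols),
    sprintf('  <key id="%s" for="node" attr.name="%s" attr.type="string"/>',
            chr_cols, chr_cols),
    '  <key id="distance" for="edge" attr.name="distance" attr.type="double"/>',
    if ("psi" %in% names(edges))
      '  <key id="psi" for="edge" attr.name="psi" attr.type="double"/>'
  )
  node_xml <- vapply(seq_len(nrow(nodes)), function(i) {
    data <- c(
      vapply(num_cols, function(cc) sprintf(
        '      <data key="%s">%s</data>', cc,
        format(nodes[[cc]][i], digits = 15)), character(1)),
      vapply(chr_cols, function(cc) sprintf(
        '      <data key="%s">%s</data>', cc,
        xml_escape(nodes[[cc]][i])), character(1))
    )
    paste(c(sprintf('    <node id="%s">', xml_escape(nodes$pocket_id[i])),
            data, "    </node>"), collapse = "\n")
  }, character(1))
  edge_xml <- vapply(seq_len(nrow(edges)), function(i) {
    data <- sprintf('      <data key="distance">%s</data>',
                    format(edges$distance[i], digits = 15))
    if ("psi" %in% names(edges)) {
      data <- c(data, sprintf('      <data key="psi">%s</data>',
                              format(edges$psi[i], digits = 15)))
    }
    paste(c(sprintf('    <edge source="%s" target="%s">',
                    xml_escape(edges$source[i]),
                    xml_escape(edges$target[i])),
            data, "    </edge>"), collapse = "\n")
  }, character(1))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    keydefs,
    '  <graph id="pocketome" edgedefault="undirected">',
    node_xml, edge_xml,
    "  </graph>", "</graphml>"), path)
  invisible(path)
}
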