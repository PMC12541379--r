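# Export the hierarchy as a rooted tree network viewable in Cytoscape:
# cluster nodes carry their size and the distance scale at which they
# appear; leaf nodes carry the accession and all annotation columns.

#' Export a hierarchy as a tree network
#'
#' @param h A `phage_hierarchy` from [build_hierarchy()].
#' @param annotations Optional annotation tibble (`accession` + columns to
#'   join onto leaves). Leaves without an annotation row are exported with
#'   the sentinel `"unclassified"` and a warning.
#' @param path Output file path.
#' @param format `"graphml"`, `"sif"` or `"edge-tsv"`. The tabular formats
#'   additionally write `<path>.nodes.tsv` with the node attributes.
#' @return `path`, invisibly.
#' @export
export_tree_network <- function(h, annotations = NULL, path,
                                format = c("graphml", "sif", "edge-tsv")) {
  format <- match.arg(format)
  g <- tree_graph(h, annotations)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    edges <- igraph::as_data_frame(g, what = "edges")
    nodes <- igraph::as_data_frame(g, what = "vertices")
    if (format == "sif") {
      writeLines(paste(edges$from, "child", edges$to), path)
    } else {
      readr::write_tsv(as_tibble(edges), path)
    }
    readr::write_tsv(as_tibble(nodes), paste0(path, ".nodes.tsv"))
  }
  invisible(path)
}

#' Build the igraph tree underlying [export_tree_network()]
#'
#' @inheritParams export_tree_network
#' @return A directed igraph with parent-to-child edges, exactly one root,
#'   one leaf vertex per clustered accession.
#' @export
tree_graph <- function(h, annotations = NULL) {
  nodes <- hierarchy_nodes(h)
  nodes$name <- ifelse(nodes$type == "leaf", nodes$accession,
                       sprintf("cluster_%04d", nodes$node - h$n))
  if (!is.null(annotations)) {
    ann_cols <- setdiff(names(annotations), "accession")
    missing <- setdiff(nodes$accession[nodes$type == "leaf"], annotations$accession)
    if (length(missing) > 0L) {
      warn(sprintf("%d leaf accession(s) missing from annotations; exported with sentinel values",
                   length(missing)))
    }
    idx <- match(nodes$accession, annotations$accession)
    for (col in ann_cols) {
      vals <- as.character(annotations[[col]][idx])
      vals[nodes$type == "leaf" & is.na(vals)] <- UNCLASSIFIED
      nodes[[col]] <- vals
    }
  }
  edges <- nodes[!is.na(nodes$parent), c("parent", "node")]
  vertex_df <- data.frame(
    name = nodes$name,
    type = nodes$type,
    height = nodes$height,
    size = nodes$n_leaves,
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(nodes), c("node", "type", "accession", "height",
                                   "n_leaves", "parent", "name"))
  for (col in extra) vertex_df[[col]] <- ifelse(is.na(nodes[[col]]), "", nodes[[col]])
  igraph::graph_from_data_frame(
    d = data.frame(from = nodes$name[edges$parent], to = nodes$name[edges$node]),
    directed = TRUE,
    vertices = vertex_df
  )
}
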