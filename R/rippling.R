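# Membrane-rippling graphs: nodes at the stromal ends of transmembrane
# helices (projected onto the midplane), colour-binned by helix height, with
# edges between neighbouring helices carrying the absolute height difference
# (the local hydrophobic mismatch).

HEIGHT_BIN_BREAKS <- seq(20, 45, by = 5)  # A; <20 clamps low, >=45 is "45+"
DELTA_BIN_BREAKS <- seq(5, 20, by = 5)    # A; <5 suppressed, >=20 is "20+"

#' Height bin index under the 5-Angstrom binning
#'
#' Bins are \[20,25), \[25,30), ..., \[40,45), and 45+; heights below 20 clamp
#' into the lowest bin.
#'
#' @param height helix height(s), Angstrom.
#' @return integer bin index (1 = lowest).
#' @export
height_bin <- function(height) {
  pmin(pmax(findInterval(height, HEIGHT_BIN_BREAKS), 1L),
       length(HEIGHT_BIN_BREAKS))
}

delta_bin <- function(delta) {
  pmin(pmax(findInterval(delta, DELTA_BIN_BREAKS), 0L),
       length(DELTA_BIN_BREAKS))
}

# 2-D coordinates of a point in the midplane (orthonormal in-plane basis)
midplane_basis <- function(frame) {
  n <- frame$normal
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(ref - sum(ref * n) * n)
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  rbind(u, v)
}

#' Build a membrane-rippling graph
#'
#' Nodes sit at the stromal-end projections of transmembrane helices onto the
#' membrane midplane; an undirected edge joins two helices whose projections
#' lie within `neighbor_cutoff`. Edge `delta_height` is the absolute height
#' difference; differences below 5 A are retained but flagged `suppressed`
#' (the published display convention hides them).
#'
#' @param measures list of `tm_helix_measure` (>= 2).
#' @param frame a [membrane_frame()].
#' @param neighbor_cutoff neighbour distance in the midplane, Angstrom.
#' @param structure_id provenance tag.
#' @return an object of class `ripple_graph` with data.frames `nodes` and
#'   `edges`.
#' @export
build_ripple_graph <- function(measures, frame, neighbor_cutoff = 16,
                               structure_id = NA_character_) {
  if (length(measures) < 2L) stop("need >= 2 transmembrane helices")
  # deterministic node order: chain, then residue_start
  ord <- order(vapply(measures, function(m) m$helix$chain_id, ""),
               vapply(measures, function(m) m$helix$residue_start, 0L))
  measures <- measures[ord]
  B <- midplane_basis(frame)
  proj <- t(vapply(measures, function(m) {
    drop(B %*% (m$stromal_end - frame$midplane_point))
  }, numeric(2)))
  nodes <- data.frame(
    id = seq_along(measures),
    chain_id = vapply(measures, function(m) m$helix$chain_id, ""),
    subunit = vapply(measures, function(m) m$subunit_label, ""),
    residue_start = vapply(measures, function(m) m$helix$residue_start, 0L),
    residue_end = vapply(measures, function(m) m$helix$residue_end, 0L),
    x = proj[, 1], y = proj[, 2],
    height = vapply(measures, function(m) m$height, 0),
    stringsAsFactors = FALSE
  )
  nodes$height_bin <- height_bin(nodes$height)
  d2 <- as.matrix(dist(proj))
  pair <- which(upper.tri(d2) & d2 <= neighbor_cutoff, arr.ind = TRUE)
  if (nrow(pair)) {
    delta <- abs(nodes$height[pair[, 1]] - nodes$height[pair[, 2]])
    edges <- data.frame(source = pair[, 1], target = pair[, 2],
                        distance = d2[pair], delta_height = delta,
                        delta_bin = delta_bin(delta),
                        suppressed = delta < 5)
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(source = integer(), target = integer(),
                        distance = numeric(), delta_height = numeric(),
                        delta_bin = integer(), suppressed = logical())
  }
  structure(list(nodes = nodes, edges = edges, frame = frame,
                 provenance = list(structure_id = structure_id,
                                   neighbor_cutoff = neighbor_cutoff)),
            class = "ripple_graph")
}

#' @export
print.ripple_graph <- function(x, ...) {
  cat(sprintf("<ripple_graph> %d helices, %d neighbour edges (cutoff %.1f A)\n",
              nrow(x$nodes), nrow(x$edges), x$provenance$neighbor_cutoff))
  invisible(x)
}

#' Hydrophobic mismatch between two subunit groups
#'
#' Computes a statistic over the height differences of neighbour edges with
#' one endpoint in each group.
#'
#' @param graph a [build_ripple_graph()] result.
#' @param group_a,group_b character vectors of subunit labels (or chain ids).
#' @param statistic `"max"`, `"mean"` or `"min"`.
#' @param by match groups by `"subunit"` label or `"chain_id"`.
#' @return mismatch in Angstrom.
#' @export
mismatch_between <- function(graph, group_a, group_b,
                             statistic = c("max", "mean", "min"),
                             by = c("subunit", "chain_id")) {
  statistic <- match.arg(statistic)
  by <- match.arg(by)
  key <- graph$nodes[[by]]
  in_a <- graph$nodes$id[key %in% group_a]
  in_b <- graph$nodes$id[key %in% group_b]
  if (!length(in_a) || !length(in_b)) {
    stop("group without nodes in graph: ",
         if (!length(in_a)) paste(group_a, collapse = ",") else
           paste(group_b, collapse = ","))
  }
  e <- graph$edges
  cross <- (e$source %in% in_a & e$target %in% in_b) |
           (e$source %in% in_b & e$target %in% in_a)
  if (!any(cross)) {
    stop("no neighbour edge between groups '",
         paste(group_a, collapse = ","), "' and '",
         paste(group_b, collapse = ","), "'")
  }
  d <- e$delta_height[cross]
  switch(statistic, max = max(d), mean = mean(d), min = min(d))
}

#' Export a rippling graph
#'
#' @param graph a `ripple_graph`.
#' @param path output path; for `"csv"` the path is used as a prefix and two
#'   files `<path>_nodes.csv` / `<path>_edges.csv` are written.
#' @param format `"json"`, `"graphml"` or `"csv"`.
#' @return the path(s) written, invisibly.
#' @export
export_graph <- function(graph, path, format = c("json", "graphml", "csv")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown graph format: ",
                                              format[1]))
  if (format == "json") {
    payload <- list(nodes = graph$nodes, edges = graph$edges,
                    frame = list(normal = graph$frame$normal,
                                 midplane_point = graph$frame$midplane_point,
                                 stromal_sign = graph$frame$stromal_sign),
                    provenance = graph$provenance)
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                         dataframe = "columns", null = "null", na = "null")
    return(invisible(path))
  }
  if (format == "graphml") {
    write_graphml(graph$nodes, graph$edges, path)
    return(invisible(path))
  }
  paths <- paste0(path, c("_nodes.csv", "_edges.csv"))
  write.csv(graph$nodes, paths[1], row.names = FALSE)
  write.csv(graph$edges, paths[2], row.names = FALSE)
  invisible(paths)
}

#' Import a rippling graph written as JSON
#' @param path path written by [export_graph()] with `format = "json"`.
#' @return a `ripple_graph`.
#' @export
import_graph <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(p$nodes, stringsAsFactors = FALSE)
  edges <- if (length(p$edges) && length(p$edges$source)) {
    as.data.frame(p$edges, stringsAsFactors = FALSE)
  } else {
    data.frame(source = integer(), target = integer(), distance = numeric(),
               delta_height = numeric(), delta_bin = integer(),
               suppressed = logical())
  }
  frame <- membrane_frame(p$frame$normal, p$frame$midplane_point,
                          p$frame$stromal_sign)
  structure(list(nodes = nodes, edges = edges, frame = frame,
                 provenance = p$provenance), class = "ripple_graph")
}

write_graphml <- function(nodes, edges, path) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  node_attrs <- setdiff(names(nodes), "id")
  edge_attrs <- setdiff(names(edges), c("source", "target"))
  for (a in node_attrs) {
    xml2::xml_add_child(doc, "key", id = paste0("n_", a), `for` = "node",
                        attr.name = a,
                        attr.type = if (is.numeric(nodes[[a]])) "double" else "string")
  }
  for (a in edge_attrs) {
    xml2::xml_add_child(doc, "key", id = paste0("e_", a), `for` = "edge",
                        attr.name = a,
                        attr.type = if (is.numeric(edges[[a]])) "double" else "string")
  }
  g <- xml2::xml_add_child(doc, "graph", id = "ripple", edgedefault = "undirected")
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = paste0("n", nodes$id[i]))
    for (a in node_attrs) {
      d <- xml2::xml_add_child(nd, "data", key = paste0("n_", a))
      xml2::xml_text(d) <- as.character(nodes[[a]][i])
    }
  }
  for (i in seq_len(nrow(edges))) {
    ed <- xml2::xml_add_child(g, "edge",
                              source = paste0("n", edges$source[i]),
                              target = paste0("n", edges$target[i]))
    for (a in edge_attrs) {
      d <- xml2::xml_add_child(ed, "data", key = paste0("e_", a))
      xml2::xml_text(d) <- as.character(edges[[a]][i])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
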