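#' Annotated secretion network graph
#'
#' Builds the secretion network: gray intracellular precursor nodes
#' (glucose, pyruvate, acetyl-CoA, oxaloacetate/aspartate, succinyl-CoA,
#' serine cycle, purine) connected by fixed backbone edges, plus one edge
#' from each metabolite's precursor node to the secreted metabolite,
#' annotated with its percent mole-carbon flux, a shading value in [0, 1]
#' proportional to flux magnitude, and (optionally) its change versus
#' control coloured green (increase), red (decrease) or gray (no change).
#'
#' @param map a [FluxMap-class] (annotates secreted metabolites present in
#'   it); may be NULL for an unannotated (all-gray) topology graph.
#' @param changes optional named character vector
#'   (`increase`/`decrease`/`no_change`) per metabolite, e.g. from
#'   [secretionChanges()].
#' @param registry metabolite registry (provides the precursor node of each
#'   metabolite).
#' @param topology backbone edge table, see [defaultTopology()].
#' @return an [igraph::igraph] graph with vertex attributes `kind`
#'   (`node`/`metabolite`), `flux`, `shading`, and edge attributes `flux`,
#'   `change`, `color`.
#' @export
networkMap <- function(map = NULL, changes = NULL,
                       registry = defaultRegistry(),
                       topology = defaultTopology()) {
  secreted <- registry[registry$secreted, ]
  if (anyDuplicated(secreted$metabolite))
    stop("a secreted metabolite maps to more than one precursor node")
  fl <- if (is.null(map)) numeric(0) else fluxes(map)
  nodes <- sort(unique(c(topology$from, topology$to)))
  mets <- sort(secreted$metabolite)
  unknown_nodes <- setdiff(secreted$network_node, nodes)
  if (length(unknown_nodes))
    stop("registry references network node(s) absent from topology: ",
         paste(unknown_nodes, collapse = ", "))

  vertices <- data.frame(
    name = c(nodes, mets),
    kind = c(rep("node", length(nodes)), rep("metabolite", length(mets))),
    stringsAsFactors = FALSE)
  vflux <- stats::setNames(rep(NA_real_, nrow(vertices)), vertices$name)
  vflux[names(fl)[names(fl) %in% mets]] <- fl[names(fl) %in% mets]
  maxf <- suppressWarnings(max(vflux, na.rm = TRUE))
  vertices$flux <- unname(vflux)
  vertices$shading <- ifelse(is.na(vflux) | maxf <= 0, 0, vflux / maxf)
  vertices$color <- ifelse(vertices$kind == "node", "gray", "black")

  sec_edges <- data.frame(
    from = secreted$network_node[match(mets, secreted$metabolite)],
    to = mets, stringsAsFactors = FALSE)
  edges <- rbind(
    data.frame(from = topology$from, to = topology$to,
               stringsAsFactors = FALSE),
    sec_edges)
  edges <- edges[order(edges$from, edges$to), ]
  eflux <- ifelse(edges$to %in% names(fl), fl[edges$to], NA_real_)
  chg <- rep("no_change", nrow(edges))
  if (!is.null(changes)) {
    bad <- setdiff(unique(changes), c("increase", "decrease", "no_change"))
    if (length(bad)) stop("unknown change label(s): ", paste(bad, collapse = ", "))
    hit <- edges$to %in% names(changes)
    chg[hit] <- changes[edges$to[hit]]
  }
  edges$flux <- unname(eflux)
  edges$change <- chg
  edges$color <- c(increase = "green", decrease = "red",
                   no_change = "gray")[chg]

  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}

#' Export a network graph to DOT or GraphML
#'
#' Output is deterministic: vertices and edges are in the stable sorted
#' order fixed by [networkMap()], so two calls on the same input produce
#' byte-identical files.
#'
#' @param graph an igraph graph from [networkMap()].
#' @param path output file path.
#' @param format `"dot"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(graph, path, format = c("dot", "graphml")) {
  if (!format[1] %in% c("dot", "graphml"))
    stop("unknown export format: ", format[1])
  format <- match.arg(format)
  # igraph's writers choke on NA attributes in DOT; replace with sentinels
  g <- graph
  for (attr in igraph::vertex_attr_names(g)) {
    v <- igraph::vertex_attr(g, attr)
    if (is.numeric(v)) v[is.na(v)] <- 0 else v[is.na(v)] <- ""
    g <- igraph::set_vertex_attr(g, attr, value = v)
  }
  for (attr in igraph::edge_attr_names(g)) {
    v <- igraph::edge_attr(g, attr)
    if (is.numeric(v)) v[is.na(v)] <- 0 else v[is.na(v)] <- ""
    g <- igraph::set_edge_attr(g, attr, value = v)
  }
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Per-time-point network frames
#'
#' Static stand-in for an animated secretion map: assuming linear
#' accumulation of secreted products, writes one graph file per time
#' fraction with fluxes scaled by the accumulation ramp.
#'
#' @param map a [FluxMap-class] endpoint map.
#' @param out_dir output directory.
#' @param frames number of frames (time fractions 1/frames ... 1).
#' @param format `"dot"` or `"graphml"`.
#' @param ... passed to [networkMap()].
#' @return character vector of written file paths.
#' @export
exportNetworkFrames <- function(map, out_dir, frames = 5,
                                format = c("dot", "graphml"), ...) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(frames)
  for (i in seq_len(frames)) {
    g_frac <- i / frames
    frame_map <- methods::new("FluxMap",
      fluxes = fluxes(map),  # relative shares are time-invariant
      co2_percent = co2Percent(map), biomass_percent = biomassPercent(map),
      basis = fluxBasis(map), clamped = map@clamped)
    g <- networkMap(frame_map, ...)
    g <- igraph::set_vertex_attr(g, "shading",
      value = igraph::vertex_attr(g, "shading") * g_frac)
    paths[i] <- file.path(out_dir, sprintf("frame_%02d.%s", i, format))
    exportNetwork(g, paths[i], format)
  }
  paths
}
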