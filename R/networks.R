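## Typed interaction networks: filtering by edge type, the physical-edge node
## fraction, shared-domain network assembly from a domain-interaction map, and
## SIF/GraphML I/O.

#' Filter a typed network by edge type
#'
#' Keeps only edges whose type is in `types`; all nodes are retained (nodes
#' left without edges can be listed with [isolatedNodes()]). Filtering is
#' idempotent.
#'
#' @param net an [InteractionNetwork-class].
#' @param types character subset of [edgeTypeVocabulary()].
#' @return the filtered [InteractionNetwork-class].
#' @export
filterEdges <- function(net, types) {
  stopifnot(is(net, "InteractionNetwork"))
  bad <- setdiff(types, edgeTypeVocabulary())
  if (length(bad))
    stop(sprintf("unknown edge type(s): %s", paste(bad, collapse = ", ")))
  e <- net@edges[net@edges$type %in% types, , drop = FALSE]
  rownames(e) <- NULL
  new("InteractionNetwork", nodes = net@nodes, edges = e,
      nodeDomains = net@nodeDomains)
}

#' Nodes without any incident edge
#' @param net an [InteractionNetwork-class].
#' @return character vector of isolated node names.
#' @export
isolatedNodes <- function(net) {
  stopifnot(is(net, "InteractionNetwork"))
  setdiff(net@nodes, unique(c(net@edges$from, net@edges$to)))
}

#' Fraction of nodes with at least one physical edge
#'
#' The "physical interconnectivity" summary: the fraction of network nodes
#' incident to one or more edges of type "physical".
#'
#' @param net an [InteractionNetwork-class] with >= 1 node.
#' @return a fraction in [0, 1].
#' @export
physicalFraction <- function(net) {
  stopifnot(is(net, "InteractionNetwork"))
  if (length(net@nodes) == 0L) stop("empty network")
  phys <- net@edges[net@edges$type == "physical", , drop = FALSE]
  touched <- unique(c(phys$from, phys$to))
  length(intersect(net@nodes, touched)) / length(net@nodes)
}

#' Build the shared-domain network from a domain-interaction map
#'
#' An edge (u, v) of type "shared_domain" is created iff some domain of u and
#' some domain of v form an interacting pair in the map; a domain paired with
#' itself counts (e.g. LIM-LIM). Proteins with empty domain annotations
#' cannot participate.
#'
#' @param proteinDomains named list: protein symbol -> character vector of
#'   domain identifiers.
#' @param dmap a [DomainInteractionMap-class].
#' @return an [InteractionNetwork-class] whose nodes are the annotated
#'   proteins, with `nodeDomains` carried along.
#' @examples
#' dmap <- DomainInteractionMap(data.frame(a = "LIM", b = "LIM"))
#' net <- domainNetwork(list(LASP1 = "LIM", TES = "LIM"), dmap)
#' networkEdges(net)
#' @export
domainNetwork <- function(proteinDomains, dmap) {
  stopifnot(is(dmap, "DomainInteractionMap"))
  if (is.null(names(proteinDomains)))
    stop("'proteinDomains' must be a named list")
  prots <- names(proteinDomains)
  key <- paste(dmap@pairs$domain_a, dmap@pairs$domain_b, sep = "\r")
  edges <- NULL
  if (length(prots) >= 2L) {
    cmb <- utils::combn(prots, 2L)
    hit <- vapply(seq_len(ncol(cmb)), function(k) {
      du <- proteinDomains[[cmb[1L, k]]]
      dv <- proteinDomains[[cmb[2L, k]]]
      if (!length(du) || !length(dv)) return(FALSE)
      any(paste(rep(du, each = length(dv)), dv, sep = "\r") %in% key)
    }, logical(1L))
    if (any(hit)) {
      edges <- data.frame(from = cmb[1L, hit], to = cmb[2L, hit],
                          type = "shared_domain", stringsAsFactors = FALSE)
    }
  }
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        type = character())
  }
  InteractionNetwork(nodes = prots, edges = edges,
                     nodeDomains = proteinDomains)
}

#' Read a domain-interaction map from a two-column CSV
#' @param path CSV whose first two columns are interacting domain pairs.
#' @return a [DomainInteractionMap-class] (symmetric closure).
#' @export
readDomainMap <- function(path) {
  DomainInteractionMap(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a typed network in SIF format
#'
#' SIF lines are `node <TAB> type <TAB> node`; a line holding a single node
#' name declares an isolated node.
#'
#' @param path SIF file path.
#' @return an [InteractionNetwork-class].
#' @export
readSIF <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  nodes <- character(); from <- character(); to <- character()
  type <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) == 1L) {
      nodes <- c(nodes, f)
    } else if (length(f) >= 3L) {
      from <- c(from, rep(f[1L], length(f) - 2L))
      type <- c(type, rep(f[2L], length(f) - 2L))
      to <- c(to, f[3:length(f)])
    } else {
      stop(sprintf("malformed SIF line %d: %s", i, lines[i]))
    }
  }
  InteractionNetwork(nodes = nodes,
                     edges = data.frame(from = from, to = to, type = type,
                                        stringsAsFactors = FALSE))
}

#' Write a typed network in SIF format
#' @param net an [InteractionNetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSIF <- function(net, path) {
  stopifnot(is(net, "InteractionNetwork"))
  e <- net@edges
  lines <- c(if (nrow(e)) paste(e$from, e$type, e$to, sep = "\t"),
             isolatedNodes(net))
  writeLines(lines, path)
  invisible(path)
}

#' Convert to / from igraph
#'
#' @param net an [InteractionNetwork-class].
#' @return `asIgraph`: an undirected igraph graph with edge attribute `type`.
#' @export
asIgraph <- function(net) {
  stopifnot(is(net, "InteractionNetwork"))
  igraph::graph_from_data_frame(net@edges, directed = FALSE,
                                vertices = data.frame(name = net@nodes))
}

#' @rdname asIgraph
#' @param g an undirected igraph graph with a `type` edge attribute.
#' @return `fromIgraph`: an [InteractionNetwork-class].
#' @export
fromIgraph <- function(g) {
  e <- igraph::as_data_frame(g, what = "edges")
  if (!nrow(e)) {
    edges <- data.frame(from = character(), to = character(),
                        type = character())
  } else {
    if (is.null(e$type)) stop("igraph edges need a 'type' attribute")
    edges <- data.frame(from = e$from, to = e$to, type = e$type,
                        stringsAsFactors = FALSE)
  }
  InteractionNetwork(nodes = igraph::V(g)$name, edges = edges)
}

#' Read / write a typed network as GraphML
#' @param path GraphML file path.
#' @return `readGraphML`: an [InteractionNetwork-class].
#' @export
readGraphML <- function(path) {
  fromIgraph(igraph::read_graph(path, format = "graphml"))
}

#' @rdname readGraphML
#' @param net an [InteractionNetwork-class].
#' @return `writeGraphML`: `path`, invisibly.
#' @export
writeGraphML <- function(net, path) {
  igraph::write_graph(asIgraph(net), path, format = "graphml")
  invisible(path)
}
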