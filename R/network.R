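#' Road network of travel times
#'
#' A `road_network` couples a node table (planar km coordinates) with an
#' undirected edge list whose weights are car travel times in minutes. It is
#' the substrate for both the competition covariate (minimal travel time
#' between obstetric sites) and the accessibility surfaces.
#'
#' @param nodes data.frame with columns `node_id`, `x`, `y` (km).
#' @param edges data.frame with columns `from`, `to`, `time_min`; every
#'   endpoint must appear in `nodes` and every weight must be strictly
#'   positive.
#' @return An object of class `road_network`: a list with elements `nodes`,
#'   `edges` and `graph` (an [igraph][igraph::graph_from_data_frame] object
#'   whose vertex names are the node ids and whose `weight` attribute is the
#'   travel time).
#' @export
road_network <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  need_n <- c("node_id", "x", "y")
  need_e <- c("from", "to", "time_min")
  miss <- setdiff(need_n, names(nodes))
  if (length(miss)) stop("nodes is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(need_e, names(edges))
  if (length(miss)) stop("edges is missing column(s): ", paste(miss, collapse = ", "))
  nodes$node_id <- as.character(nodes$node_id)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (anyDuplicated(nodes$node_id)) stop("duplicate node_id in nodes")
  if (nrow(edges) > 0) {
    unknown <- setdiff(c(edges$from, edges$to), nodes$node_id)
    if (length(unknown)) {
      stop("edge endpoint(s) not in node table: ", paste(utils::head(unknown, 5), collapse = ", "))
    }
    if (any(!is.finite(edges$time_min)) || any(edges$time_min <= 0)) {
      stop("all edge travel times must be finite and strictly positive")
    }
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "time_min")],
    directed = FALSE,
    vertices = nodes[, c("node_id", "x", "y")]
  )
  igraph::E(g)$weight <- edges$time_min
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat("road_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  connected:", network_is_connected(x), "\n")
  invisible(x)
}

#' Is the network a single connected component?
#'
#' @param network a [road_network()].
#' @return Logical scalar.
#' @export
network_is_connected <- function(network) {
  stopifnot(inherits(network, "road_network"))
  igraph::count_components(network$graph) == 1L
}

#' Snap planar points to their nearest network node
#'
#' Brute-force nearest-neighbour search in Euclidean km, chunked to bound
#' memory. Access time from the point to the node is treated as zero; the
#' snap distance is returned so callers can add an access-time penalty.
#'
#' @param network a [road_network()].
#' @param x,y numeric vectors of equal length (km coordinates).
#' @return data.frame with columns `node_id` and `snap_km`.
#' @export
snap_to_network <- function(network, x, y) {
  stopifnot(inherits(network, "road_network"), length(x) == length(y))
  nd <- network$nodes
  n <- length(x)
  out_id <- character(n)
  out_d <- numeric(n)
  chunk <- max(1L, floor(4e6 / max(1L, nrow(nd))))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    d2 <- outer(x[idx], nd$x, "-")^2 + outer(y[idx], nd$y, "-")^2
    j <- max.col(-d2, ties.method = "first")
    out_id[idx] <- nd$node_id[j]
    out_d[idx] <- sqrt(d2[cbind(seq_along(idx), j)])
  }
  data.frame(node_id = out_id, snap_km = out_d)
}
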