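#' Facility set for accessibility analysis
#'
#' The active obstetric facilities considered by a travel-time surface:
#' site id, network node, annual live births and pediatrics availability
#' (the two attributes regionalization scenarios filter on).
#'
#' @param sites data.frame with columns `site_id`, `node_id`, `live_births`,
#'   `has_pediatrics`.
#' @param network a [road_network()]; every `node_id` must exist in it.
#' @return data.frame of class `facility_set`.
#' @export
facility_set <- function(sites, network) {
  need <- c("site_id", "node_id", "live_births", "has_pediatrics")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("sites is missing column(s): ", paste(miss, collapse = ", "))
  stopifnot(inherits(network, "road_network"))
  unknown <- setdiff(as.character(sites$node_id), network$nodes$node_id)
  if (length(unknown)) stop("facility node(s) not in network: ", unknown[1L])
  out <- as.data.frame(sites)[, need]
  out$node_id <- as.character(out$node_id)
  class(out) <- c("facility_set", "data.frame")
  out
}

#' Minimum travel time from every network node to the nearest facility
#'
#' For each node, the minimum over all facilities of the shortest-path
#' travel time (computed from the facility side; the result equals the
#' per-facility minimum by symmetry of the undirected network). Nodes
#' unreachable from every facility get `+Inf`.
#'
#' @param network a [road_network()].
#' @param facility_nodes character vector of facility node ids (duplicates
#'   allowed). An empty set yields all-`Inf` with a warning.
#' @return named numeric vector of minutes, one entry per network node.
#' @export
shortest_time_map <- function(network, facility_nodes) {
  stopifnot(inherits(network, "road_network"))
  ids <- network$nodes$node_id
  facility_nodes <- unique(as.character(facility_nodes))
  if (length(facility_nodes) == 0L) {
    warning("empty facility set: all nodes unreachable")
    return(stats::setNames(rep(Inf, length(ids)), ids))
  }
  unknown <- setdiff(facility_nodes, ids)
  if (length(unknown)) stop("facility node(s) not in network: ", unknown[1L])
  d <- igraph::distances(network$graph, v = facility_nodes, to = ids,
                         weights = igraph::E(network$graph)$weight)
  res <- if (nrow(d) == 1L) d[1L, ] else apply(d, 2L, min)
  stats::setNames(as.numeric(res), ids)
}

#' Sample uniform points over a rectangular region
#'
#' Seeded uniform sampling over the bounding box; when a network is given,
#' every point is snapped to its nearest node and the snap distance is
#' recorded.
#'
#' @param bbox numeric `c(xmin, xmax, ymin, ymax)` with positive area.
#' @param n number of points (>= 1).
#' @param seed integer seed.
#' @param network optional [road_network()] for snapping.
#' @return data.frame with `x`, `y` and, when snapped, `node_id`, `snap_km`.
#' @export
sample_points <- function(bbox, n, seed, network = NULL) {
  if (length(bbox) == 4L && is.null(names(bbox))) {
    names(bbox) <- c("xmin", "xmax", "ymin", "ymax")
  }
  if (bbox["xmax"] <= bbox["xmin"] || bbox["ymax"] <= bbox["ymin"]) {
    stop("degenerate region: bbox must have positive area")
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (missing(seed) || is.null(seed)) stop("an integer seed is mandatory")
  set.seed(as.integer(seed))
  pts <- data.frame(x = stats::runif(n, bbox["xmin"], bbox["xmax"]),
                    y = stats::runif(n, bbox["ymin"], bbox["ymax"]))
  if (!is.null(network)) {
    sn <- snap_to_network(network, pts$x, pts$y)
    pts$node_id <- sn$node_id
    pts$snap_km <- sn$snap_km
  }
  pts
}

#' Classify a travel time into threshold bands
#'
#' `under30` for times strictly below the lower threshold, `band30to40` for
#' times between the thresholds inclusive, `over40` beyond the upper
#' threshold; unreachable locations (`+Inf`) are `over40`.
#'
#' @param minutes numeric vector of non-negative travel times (or `Inf`).
#' @param thresholds increasing pair, default `c(30, 40)` minutes.
#' @return factor with levels `under30`, `band30to40`, `over40`.
#' @export
classify_time <- function(minutes, thresholds = c(30, 40)) {
  if (anyNA(minutes)) stop("travel times must not be missing")
  if (any(minutes < 0)) stop("travel times must be non-negative")
  stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2])
  bands <- ifelse(minutes < thresholds[1], "under30",
                  ifelse(minutes <= thresholds[2], "band30to40", "over40"))
  factor(bands, levels = c("under30", "band30to40", "over40"))
}

#' Regionalization scenario
#'
#' A named restriction of the facility set: keep only facilities with a
#' pediatrics department, and/or only facilities with at least a minimum
#' annual number of live births (inclusive). With both criteria off the
#' scenario is the explicit "all facilities" baseline.
#'
#' @param name scenario label.
#' @param require_pediatrics keep only facilities with pediatrics?
#' @param min_live_births inclusive lower bound on annual live births, or
#'   `NULL` for no bound.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, require_pediatrics = FALSE, min_live_births = NULL) {
  if (missing(name) || !nzchar(name)) {
    stop("a scenario needs a name (use e.g. 'all' for the unrestricted baseline)")
  }
  if (!is.null(min_live_births) && min_live_births < 0) {
    stop("min_live_births must be non-negative")
  }
  structure(list(name = name,
                 require_pediatrics = isTRUE(require_pediatrics),
                 min_live_births = min_live_births),
            class = "scenario_spec")
}

#' Apply a regionalization scenario to a facility set
#'
#' @param facilities a [facility_set()] (or compatible data.frame).
#' @param spec a [scenario_spec()].
#' @return the facility subset satisfying all active criteria (possibly
#'   empty, with a warning).
#' @export
apply_scenario <- function(facilities, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  keep <- rep(TRUE, nrow(facilities))
  if (spec$require_pediatrics) {
    keep <- keep & (facilities$has_pediatrics %in% c(TRUE, "yes"))
  }
  if (!is.null(spec$min_live_births)) {
    keep <- keep & facilities$live_births >= spec$min_live_births
  }
  out <- facilities[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("scenario '", spec$name, "' leaves no facility")
  out
}

#' Travel-time accessibility surface
#'
#' Samples points over the region, snaps them to the network, and annotates
#' each with the minimum travel time to the nearest facility and its
#' threshold band.
#'
#' @param network a [road_network()].
#' @param facilities a [facility_set()] (or data.frame with `node_id`).
#' @param n number of sampled points (the reference analysis uses 100,000).
#' @param seed integer seed.
#' @param bbox sampling rectangle; defaults to the network's node extent.
#' @param points optional pre-sampled points (from [sample_points()] with
#'   snapping); overrides `n`/`seed`/`bbox`.
#' @param thresholds travel-time band boundaries in minutes.
#' @return data.frame of class `access_surface` with columns `x`, `y`,
#'   `node_id`, `snap_km`, `min_time`, `band`; attributes `n_points`,
#'   `seed`, `thresholds`.
#' @export
access_surface <- function(network, facilities, n = 10000L, seed = 1L,
                           bbox = NULL, points = NULL, thresholds = c(30, 40)) {
  stopifnot(inherits(network, "road_network"))
  fac_nodes <- if (is.data.frame(facilities)) facilities$node_id else facilities
  if (is.null(points)) {
    if (is.null(bbox)) {
      bbox <- c(xmin = min(network$nodes$x), xmax = max(network$nodes$x),
                ymin = min(network$nodes$y), ymax = max(network$nodes$y))
      # pad degenerate axes (e.g. collinear toy networks)
      if (bbox["xmax"] <= bbox["xmin"]) bbox[c("xmin", "xmax")] <- bbox["xmin"] + c(-0.5, 0.5)
      if (bbox["ymax"] <= bbox["ymin"]) bbox[c("ymin", "ymax")] <- bbox["ymin"] + c(-0.5, 0.5)
    }
    points <- sample_points(bbox, n, seed, network = network)
  } else if (is.null(points$node_id)) {
    sn <- snap_to_network(network, points$x, points$y)
    points$node_id <- sn$node_id
    points$snap_km <- sn$snap_km
  }
  tm <- shortest_time_map(network, as.character(fac_nodes))
  points$min_time <- unname(tm[points$node_id])
  points$band <- classify_time(points$min_time, thresholds)
  attr(points, "n_points") <- nrow(points)
  attr(points, "seed") <- if (is.null(points$seed)) seed else points$seed[1]
  attr(points, "thresholds") <- thresholds
  class(points) <- c("access_surface", "data.frame")
  points
}

#' Coverage report of an accessibility surface
#'
#' Fraction of sampled points in each travel-time band with binomial
#' Monte-Carlo standard errors; when a reference surface is supplied (e.g.
#' the unrestricted baseline for a scenario) the per-band deltas are
#' reported as well.
#'
#' @param surface an [access_surface()].
#' @param reference optional baseline [access_surface()] over the same
#'   points.
#' @return data.frame of class `coverage_report` with one row per band:
#'   `band`, `n`, `fraction`, `se` and (with a reference) `ref_fraction`,
#'   `delta`.
#' @export
coverage_report <- function(surface, reference = NULL) {
  if (nrow(surface) == 0L) stop("surface has no points")
  n <- nrow(surface)
  tab <- table(surface$band)
  frac <- as.numeric(tab) / n
  out <- data.frame(
    band = names(tab),
    n = as.integer(tab),
    fraction = frac,
    se = sqrt(frac * (1 - frac) / n)
  )
  if (!is.null(reference)) {
    if (nrow(reference) != n) {
      stop("reference surface must have the same number of points")
    }
    rfrac <- as.numeric(table(reference$band)) / n
    out$ref_fraction <- rfrac
    out$delta <- out$fraction - rfrac
  }
  class(out) <- c("coverage_report", "data.frame")
  out
}
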