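#' Read a hospital-site registry from CSV
#'
#' The registry CSV carries one hospital record per row. Mandatory columns:
#' `site_id`, `year`, `departments` (`;`-separated specialty codes),
#' `procedures` (`;`-separated `code:count` pairs), `ownership`
#' (`nonprofit`/`public`/`private`) and `teaching` (`no`/`yes`/`university`).
#' Recognized optional columns: `node_id`, `x`, `y`, `postal_area`,
#' `facility_type`, `whole_hospital_closed`. Unknown columns are preserved
#' untouched.
#'
#' @param path CSV file path (UTF-8, comma separator, `.` decimal mark).
#' @return registry data.frame.
#' @export
read_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  mandatory <- c("site_id", "year", "departments", "procedures", "ownership", "teaching")
  miss <- setdiff(mandatory, names(df))
  if (length(miss)) {
    stop("registry file is missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  dup <- duplicated(df[, c("site_id", "year")])
  if (any(dup)) {
    stop("duplicate (site_id, year) at data row ", which(dup)[1L], ": ",
         df$site_id[dup][1L])
  }
  yr <- suppressWarnings(as.integer(df$year))
  if (anyNA(yr)) stop("unparseable year at data row ", which(is.na(yr))[1L])
  df$year <- yr
  for (v in c("x", "y")) if (!is.null(df[[v]])) {
    num <- suppressWarnings(as.numeric(df[[v]]))
    bad <- which(is.na(num) & nzchar(df[[v]]))
    if (length(bad)) stop("unparseable '", v, "' at data row ", bad[1L])
    df[[v]] <- num
  }
  if (!is.null(df$whole_hospital_closed)) {
    w <- toupper(trimws(df$whole_hospital_closed))
    val <- w %in% c("TRUE", "T", "1", "YES")
    bad <- which(!(w %in% c("TRUE", "T", "1", "YES", "FALSE", "F", "0", "NO", "")))
    if (length(bad)) stop("unparseable 'whole_hospital_closed' at data row ", bad[1L])
    df$whole_hospital_closed <- val
  }
  df
}

#' Write a registry to CSV
#'
#' @param registry registry data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(registry, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read a road network as a node/edge CSV pair
#'
#' @param network a [road_network()].
#' @param nodes_path,edges_path output CSV paths.
#' @return paths, invisibly.
#' @export
write_network_csv <- function(network, nodes_path, edges_path) {
  stopifnot(inherits(network, "road_network"))
  utils::write.csv(network$nodes, nodes_path, row.names = FALSE)
  utils::write.csv(network$edges, edges_path, row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(nodes_path, edges_path) {
  nodes <- utils::read.csv(nodes_path, stringsAsFactors = FALSE,
                           colClasses = c(node_id = "character"))
  edges <- utils::read.csv(edges_path, stringsAsFactors = FALSE,
                           colClasses = c(from = "character", to = "character"))
  road_network(nodes, edges)
}

#' Write a road network as GeoJSON LineStrings
#'
#' One LineString feature per edge with `from`, `to` and `time_min`
#' properties. Coordinates are planar km of the synthetic region, declared
#' in the collection's `crs_note` metadata (they are not geographic).
#'
#' @param network a [road_network()].
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_network_geojson <- function(network, path) {
  stopifnot(inherits(network, "road_network"))
  nd <- network$nodes
  i <- match(network$edges$from, nd$node_id)
  j <- match(network$edges$to, nd$node_id)
  features <- lapply(seq_len(nrow(network$edges)), function(e) {
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(c(nd$x[i[e]], nd$y[i[e]]),
                                            c(nd$x[j[e]], nd$y[j[e]]))),
         properties = list(from = network$edges$from[e],
                           to = network$edges$to[e],
                           time_min = network$edges$time_min[e]))
  })
  fc <- list(type = "FeatureCollection",
             crs_note = "planar km coordinates of a synthetic region, not geographic",
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an accessibility surface as GeoJSON points
#'
#' @param surface an [access_surface()].
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_surface_geojson <- function(surface, path) {
  features <- lapply(seq_len(nrow(surface)), function(k) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(surface$x[k], surface$y[k])),
         properties = list(min_time = surface$min_time[k],
                           band = as.character(surface$band[k])))
  })
  fc <- list(type = "FeatureCollection",
             crs_note = "planar km coordinates of a synthetic region, not geographic",
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the regression table of a fitted closure model as CSV
#'
#' Columns mirror the published table layout: term, level, OR, CI bounds,
#' GVIF, raw and adjusted p. Fit statistics go to a companion CSV when
#' `stats_path` is given.
#'
#' @param fit a `closure_fit`.
#' @param path output CSV path.
#' @param stats_path optional path for the fit-statistics block.
#' @return `path`, invisibly.
#' @export
write_regression_csv <- function(fit, path, stats_path = NULL) {
  stopifnot(inherits(fit, "closure_fit"))
  tab <- fit$table[, c("term", "level", "or", "ci_low", "ci_high",
                       "gvif", "p_raw", "p_adj")]
  utils::write.csv(tab, path, row.names = FALSE)
  if (!is.null(stats_path)) {
    st <- fit$stats
    utils::write.csv(data.frame(statistic = names(st),
                                value = unlist(st, use.names = FALSE)),
                     stats_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML configuration of an end-to-end run. Mandatory: a `seed`. Recognized
#' keys: `n_sites`, `n_nodes`, `sampler_n` (surface points),
#' `density_cutpoints`, `fertility_cutpoints`, `time_thresholds`,
#' `scenarios` (list of `{name, require_pediatrics, min_live_births}`), and
#' optional `paths` (`registry_baseline`, `registry_followup`, `areas`,
#' `network_nodes`, `network_edges`) to analyse on-disk data instead of a
#' simulated region.
#'
#' @param path YAML file path.
#' @return object of class `pipeline_config` (a validated list).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pipeline_config(cfg)
}

#' @rdname read_config
#' @param config a named list of configuration values.
#' @export
pipeline_config <- function(config) {
  if (is.null(config$seed)) stop("config must set an integer 'seed'")
  defaults <- list(
    n_sites = 702L, n_nodes = 1500L, sampler_n = 10000L,
    density_cutpoints = c(100, 1000),
    fertility_cutpoints = c(1.3, 1.6),
    time_thresholds = c(30, 40),
    scenarios = list(
      list(name = "all"),
      list(name = "pediatrics_only", require_pediatrics = TRUE),
      list(name = "min600_births", min_live_births = 600)
    ),
    target_closure_rate = 0.1026
  )
  cfg <- utils::modifyList(defaults, config)
  for (k in c("density_cutpoints", "fertility_cutpoints", "time_thresholds")) {
    v <- as.numeric(unlist(cfg[[k]]))
    if (length(v) != 2L || diff(v) <= 0) stop("'", k, "' must be strictly increasing")
    cfg[[k]] <- v
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}
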