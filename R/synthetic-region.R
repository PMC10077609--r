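#' Configuration for a synthetic study region
#'
#' Describes the synthetic region from which a testable analogue of the
#' national hospital-site cohort is generated: a planar road network, area
#' cells carrying population density and fertility rate, and a baseline
#' registry of obstetric hospital sites. Defaults reproduce the marginal
#' structure of the regression sample: ownership 39.89/43.16/16.95%
#' (nonprofit/public/private), pediatrics on site 39.46%, density strata
#' 4.99/41.60/53.42% (low/medium/high), live births with median 683 and
#' IQR 450--1,126.
#'
#' @param n_sites number of obstetric hospital sites (default 702, the
#'   regression-sample size).
#' @param n_nodes number of road-network vertices; must be at least
#'   `n_sites`.
#' @param bbox numeric `c(xmin, xmax, ymin, ymax)` in km. The default
#'   600 x 800 km rectangle gives, with 702 sites, a median minimal
#'   inter-facility travel time near the observed 18.2 minutes.
#' @param attribute_marginals named list of probability vectors for
#'   `ownership`, `pediatrics`, `teaching` and `density`; each must sum to 1
#'   (within 1e-9).
#' @param births_median,births_iqr target median and quartiles of the annual
#'   live-birth distribution; a log-normal is solved from the median and the
#'   IQR ratio (see [births_lognormal_params()]).
#' @param fertility_range range of area-level total fertility rates
#'   (children per woman) sampled uniformly per area cell.
#' @param n_cells number of area cells (Voronoi regions of a node subset)
#'   used for the postal-code-style linkage of density and fertility.
#' @param speed_kmh assumed car speed converting edge length to minutes.
#' @param detour_factor multiplier on Euclidean edge length emulating the
#'   detours and sub-highway speeds of real road routing; the default 1.45
#'   reproduces the observed median minimal inter-facility travel time
#'   (18.2 min) at the default site density.
#' @param k_nearest neighbours per node in the network construction.
#' @param births_growth multiplicative growth of annual live births at
#'   surviving sites between the two reporting years (default 1.2521, the
#'   observed +25.21% change in median).
#' @param years the two reporting years.
#' @param seed integer seed; every generator is a deterministic function of
#'   the configuration and this seed.
#' @return An object of class `region_config` (a validated list).
#' @export
region_config <- function(n_sites = 702L,
                          n_nodes = 1500L,
                          bbox = c(xmin = 0, xmax = 600, ymin = 0, ymax = 800),
                          attribute_marginals = list(
                            ownership = c(nonprofit = 280, public = 303, private = 119) / 702,
                            pediatrics = c(no = 425, yes = 277) / 702,
                            teaching = c(no = 236, yes = 466) / 702,
                            density = c(low = 35, medium = 292, high = 375) / 702
                          ),
                          births_median = 683,
                          births_iqr = c(450, 1126),
                          fertility_range = c(1.1, 1.9),
                          n_cells = 120L,
                          speed_kmh = 60,
                          detour_factor = 1.45,
                          k_nearest = 4L,
                          births_growth = 1.2521,
                          years = c(2014L, 2019L),
                          seed = 1L) {
  n_sites <- as.integer(n_sites)
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_sites) || n_sites < 1L) stop("n_sites must be a positive integer")
  if (n_sites >= 2L && n_nodes < n_sites) stop("n_nodes must be at least n_sites")
  if (n_nodes < 2L) stop("n_nodes must be at least 2")
  if (length(bbox) != 4L) stop("bbox must be c(xmin, xmax, ymin, ymax)")
  bbox <- stats::setNames(as.numeric(bbox), c("xmin", "xmax", "ymin", "ymax"))
  if (bbox["xmax"] <= bbox["xmin"] || bbox["ymax"] <= bbox["ymin"]) {
    stop("bbox must have positive extent on both axes")
  }
  for (nm in c("ownership", "pediatrics", "teaching", "density")) {
    p <- attribute_marginals[[nm]]
    if (is.null(p)) stop("attribute_marginals is missing '", nm, "'")
    if (abs(sum(p) - 1) > 1e-9) stop("attribute_marginals$", nm, " must sum to 1")
    if (any(p < 0)) stop("attribute_marginals$", nm, " must be non-negative")
  }
  if (length(births_iqr) != 2L || births_iqr[1] >= births_iqr[2]) {
    stop("births_iqr must be c(q25, q75) with q25 < q75")
  }
  if (births_median <= 0) stop("births_median must be positive")
  if (fertility_range[1] <= 0 || fertility_range[1] >= fertility_range[2]) {
    stop("fertility_range must be an increasing positive pair")
  }
  if (is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    stop("an integer seed is mandatory")
  }
  structure(list(
    n_sites = n_sites, n_nodes = n_nodes, bbox = bbox,
    attribute_marginals = attribute_marginals,
    births_median = births_median, births_iqr = births_iqr,
    fertility_range = as.numeric(fertility_range),
    n_cells = as.integer(n_cells),
    speed_kmh = speed_kmh, detour_factor = detour_factor,
    k_nearest = as.integer(k_nearest),
    births_growth = births_growth,
    years = as.integer(years),
    seed = as.integer(seed)
  ), class = "region_config")
}

#' Log-normal parameters from a target median and IQR ratio
#'
#' Solves `meanlog` from the median and `sdlog` from the quartile ratio
#' (`q75/q25 = exp(2 * qnorm(0.75) * sdlog)`). With two parameters the
#' median and the IQR ratio are matched exactly; the absolute quartiles are
#' then determined (and land close to, not exactly on, the targets).
#'
#' @param median target median.
#' @param iqr numeric `c(q25, q75)`.
#' @return list with `meanlog` and `sdlog`.
#' @export
births_lognormal_params <- function(median = 683, iqr = c(450, 1126)) {
  stopifnot(median > 0, length(iqr) == 2L, iqr[1] > 0, iqr[2] > iqr[1])
  list(meanlog = log(median),
       sdlog = log(iqr[2] / iqr[1]) / (2 * stats::qnorm(0.75)))
}

#' Generate a synthetic road network
#'
#' Uniform random vertices in the bounding box joined by a k-nearest-
#' neighbour graph; if that graph is disconnected, the closest pair of
#' vertices across components is bridged repeatedly until a single component
#' remains. Edge weights are Euclidean length divided by the assumed speed,
#' in minutes. This is the simplest planar surrogate for a road network with
#' controllable density; detours arise from routing through vertices.
#'
#' @param config a [region_config()].
#' @return A connected [road_network()]. Identical configuration (including
#'   seed) yields an identical network.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "region_config"))
  n <- config$n_nodes
  if (n < 2L) stop("cannot build a connected network with fewer than 2 nodes")
  set.seed(config$seed)
  bb <- config$bbox
  x <- stats::runif(n, bb["xmin"], bb["xmax"])
  y <- stats::runif(n, bb["ymin"], bb["ymax"])
  k <- min(config$k_nearest, n - 1L)
  if (k < 1L) stop("k_nearest leaves the network unconnectable")
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  from <- integer(0); to <- integer(0)
  ord <- apply(d, 1L, function(r) order(r)[seq_len(k)])
  ord <- matrix(ord, nrow = k)
  for (j in seq_len(k)) {
    from <- c(from, seq_len(n))
    to <- c(to, ord[j, ])
  }
  lo <- pmin(from, to); hi <- pmax(from, to)
  keep <- !duplicated(cbind(lo, hi))
  lo <- lo[keep]; hi <- hi[keep]
  ids <- sprintf("N%04d", seq_len(n))
  mk_net <- function(lo, hi) {
    w <- d[cbind(lo, hi)] * config$detour_factor / config$speed_kmh * 60
    road_network(
      nodes = data.frame(node_id = ids, x = x, y = y),
      edges = data.frame(from = ids[lo], to = ids[hi], time_min = w)
    )
  }
  net <- mk_net(lo, hi)
  guard <- 0L
  while (!network_is_connected(net)) {
    comp <- igraph::components(net$graph)$membership
    comp <- comp[ids]  # align to node order
    in1 <- comp == comp[1L]
    dcross <- d[in1, !in1, drop = FALSE]
    ij <- which(dcross == min(dcross), arr.ind = TRUE)[1L, ]
    a <- which(in1)[ij[1L]]; b <- which(!in1)[ij[2L]]
    lo <- c(lo, min(a, b)); hi <- c(hi, max(a, b))
    net <- mk_net(lo, hi)
    guard <- guard + 1L
    if (guard > n) stop("failed to connect the network; parameters unsatisfiable")
  }
  net
}

#' Generate area cells with density and fertility attributes
#'
#' A coarse subset of network nodes becomes cell centres; every node is
#' assigned to its nearest centre (a Voronoi partition in Euclidean km),
#' mirroring postal-code linkage of area statistics to hospital sites. Each
#' cell draws a density stratum from the configured marginals, a raw density
#' uniform within that stratum's range, and a fertility rate uniform on
#' `fertility_range`.
#'
#' @param network a connected [road_network()].
#' @param config a [region_config()].
#' @return list with `areas` (data.frame: `postal_area`, `density_raw`,
#'   `density_category`, `fertility_rate`) and `node_area` (character vector
#'   mapping every node id to its area code).
#' @export
generate_areas <- function(network, config) {
  stopifnot(inherits(network, "road_network"), inherits(config, "region_config"))
  set.seed(config$seed + 1L)
  nd <- network$nodes
  m <- min(config$n_cells, nrow(nd))
  centre_idx <- sample.int(nrow(nd), m)
  d2 <- outer(nd$x, nd$x[centre_idx], "-")^2 + outer(nd$y, nd$y[centre_idx], "-")^2
  cell <- max.col(-d2, ties.method = "first")
  codes <- sprintf("A%03d", seq_len(m))
  # fixed composition of area types (largest-remainder rounding), random
  # spatial placement: the mix of area types is a constant of the region,
  # only their locations vary between seeds
  pr <- config$attribute_marginals$density
  strat <- sample(rep(names(pr), alloc_counts(m, pr)))
  ranges <- list(low = c(5, 100), medium = c(100.5, 1000), high = c(1000.5, 4000))
  raw <- vapply(strat, function(s) stats::runif(1, ranges[[s]][1], ranges[[s]][2]), 0)
  fert <- stats::runif(m, config$fertility_range[1], config$fertility_range[2])
  areas <- data.frame(
    postal_area = codes,
    density_raw = raw,
    density_category = strat,
    fertility_rate = fert,
    stringsAsFactors = FALSE
  )
  node_area <- stats::setNames(codes[cell], nd$node_id)
  list(areas = areas, node_area = node_area)
}

#' Place hospital sites on a synthetic network
#'
#' Draws `n_sites` distinct network nodes as hospital locations and equips
#' each with ownership, teaching status and a pediatrics department per the
#' configured marginals, and with annual live births from the solved
#' log-normal. Births are written as coded procedure entries (measures
#' accompanying birth) so the registry exercises the same operationalization
#' path as real report data.
#'
#' @param network a connected [road_network()].
#' @param config a [region_config()].
#' @param areas result of [generate_areas()]; generated on the fly if `NULL`.
#' @return A baseline-year registry data.frame (one row per site) with the
#'   columns documented in [read_registry()].
#' @export
place_hospitals <- function(network, config, areas = NULL) {
  stopifnot(inherits(network, "road_network"), inherits(config, "region_config"))
  if (!network_is_connected(network)) stop("network must be connected")
  n <- config$n_sites
  if (n > nrow(network$nodes)) stop("n_sites exceeds the number of network nodes")
  if (is.null(areas)) areas <- generate_areas(network, config)
  set.seed(config$seed + 2L)
  nd <- network$nodes
  # stratified placement: the number of sites per density stratum matches
  # the target marginal (largest remainder), so the regression sample
  # composition is a fixed property of the region, not a resampled one
  node_strat <- areas$areas$density_category[
    match(areas$node_area[nd$node_id], areas$areas$postal_area)]
  want <- alloc_counts(n, config$attribute_marginals$density)
  picked <- integer(0)
  deficit <- 0L
  for (s in names(want)) {
    pool <- setdiff(which(node_strat == s), picked)
    take <- min(want[[s]], length(pool))
    deficit <- deficit + want[[s]] - take
    if (take > 0) picked <- c(picked, pool[sample.int(length(pool), take)])
  }
  if (deficit > 0L) {
    pool <- setdiff(seq_len(nrow(nd)), picked)
    picked <- c(picked, pool[sample.int(length(pool), deficit)])
  }
  node_pick <- sort(picked)
  mar <- config$attribute_marginals
  ownership <- sample(names(mar$ownership), n, replace = TRUE, prob = mar$ownership)
  ped <- sample(names(mar$pediatrics), n, replace = TRUE, prob = mar$pediatrics) == "yes"
  teaching <- sample(names(mar$teaching), n, replace = TRUE, prob = mar$teaching)
  lp <- births_lognormal_params(config$births_median, config$births_iqr)
  births <- pmax(1L, as.integer(round(stats::rlnorm(n, lp$meanlog, lp$sdlog))))
  data.frame(
    site_id = sprintf("S%04d", seq_len(n)),
    year = config$years[1],
    node_id = nd$node_id[node_pick],
    x = nd$x[node_pick],
    y = nd$y[node_pick],
    postal_area = unname(areas$node_area[nd$node_id[node_pick]]),
    facility_type = "acute",
    departments = ifelse(ped, "2500;2400;1000", "2500;2400"),
    procedures = births_to_procedures(births),
    ownership = ownership,
    teaching = teaching,
    whole_hospital_closed = FALSE,
    stringsAsFactors = FALSE
  )
}

# Integer allocation of n among categories by largest remainder.
alloc_counts <- function(n, p) {
  cnt <- floor(n * p)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(n * p - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }
  stats::setNames(as.integer(cnt), names(p))
}

# Deterministic split of a birth total across the coded procedure entries.
births_to_procedures <- function(births) {
  c0 <- floor(0.70 * births)
  c1 <- floor(0.25 * births)
  cx <- births - c0 - c1
  paste0("9-262.0:", c0, ";9-262.1:", c1, ";9-262.x:", cx)
}

#' Generating (true) closure model
#'
#' Log-odds coefficients of the data-generating logistic closure process.
#' The default preset uses the published final-model odds ratios:
#' 0.995 per live birth, 0.357 for a pediatrics department, 0.24 and 0.251
#' for medium and high population density versus low, 0.157 per unit
#' fertility rate, 0.95 per minute of minimal inter-facility travel time;
#' ownership and teaching effects are zero. No intercept is fixed: it is
#' calibrated at simulation time so the expected closure rate matches a
#' target marginal rate (default 10.26%).
#'
#' @param intercept log-odds intercept, or `NULL` to calibrate at simulation
#'   time.
#' @param beta_births,beta_pediatrics,beta_density_medium,beta_density_high,beta_fertility,beta_mintime,beta_ownership_nonprofit,beta_ownership_public,beta_teaching
#'   log-odds effects (defaults: the preset above).
#' @return object of class `true_model`.
#' @export
true_model <- function(intercept = NULL,
                       beta_births = log(0.995),
                       beta_pediatrics = log(0.357),
                       beta_density_medium = log(0.24),
                       beta_density_high = log(0.251),
                       beta_fertility = log(0.157),
                       beta_mintime = log(0.95),
                       beta_ownership_nonprofit = 0,
                       beta_ownership_public = 0,
                       beta_teaching = 0) {
  b <- list(intercept = intercept,
            beta_births = beta_births,
            beta_pediatrics = beta_pediatrics,
            beta_density_medium = beta_density_medium,
            beta_density_high = beta_density_high,
            beta_fertility = beta_fertility,
            beta_mintime = beta_mintime,
            beta_ownership_nonprofit = beta_ownership_nonprofit,
            beta_ownership_public = beta_ownership_public,
            beta_teaching = beta_teaching)
  vals <- unlist(b[-1L])
  if (any(!is.finite(vals))) stop("all coefficients must be finite")
  if (!is.null(intercept) && !is.finite(intercept)) stop("intercept must be finite")
  structure(b, class = "true_model")
}

# Linear predictor excluding the intercept, from a covariate data.frame.
true_model_eta <- function(model, cov) {
  need <- c("live_births", "has_pediatrics", "density_category",
            "fertility_rate", "min_interfacility_time", "ownership", "teaching")
  for (nm in need) {
    bad <- which(is.na(cov[[nm]]))
    if (length(bad)) {
      stop("missing covariate '", nm, "' for site ",
           cov$site_id[bad[1L]])
    }
  }
  model$beta_births * cov$live_births +
    model$beta_pediatrics * as.numeric(cov$has_pediatrics) +
    model$beta_density_medium * as.numeric(cov$density_category == "medium") +
    model$beta_density_high * as.numeric(cov$density_category == "high") +
    model$beta_fertility * cov$fertility_rate +
    model$beta_mintime * cov$min_interfacility_time +
    model$beta_ownership_nonprofit * as.numeric(cov$ownership == "nonprofit") +
    model$beta_ownership_public * as.numeric(cov$ownership == "public") +
    model$beta_teaching * as.numeric(cov$teaching == "yes")
}

#' Calibrate the model intercept to a target marginal closure rate
#'
#' Solves `mean(plogis(a + eta)) = target_rate` for the intercept `a` over
#' the supplied covariate population.
#'
#' @param model a [true_model()].
#' @param covariates covariate data.frame (see [simulate_closures()]).
#' @param target_rate target expected closure fraction (default 0.1026, the
#'   observed marginal rate in the regression sample).
#' @return the model with its intercept set.
#' @export
calibrate_intercept <- function(model, covariates, target_rate = 0.1026) {
  stopifnot(inherits(model, "true_model"),
            target_rate > 0, target_rate < 1)
  eta <- true_model_eta(model, covariates)
  f <- function(a) mean(stats::plogis(a + eta)) - target_rate
  model$intercept <- stats::uniroot(f, c(-60, 60), tol = 1e-10)$root
  model
}

#' Simulate department closures under a logistic process
#'
#' Each site closes its obstetrics department independently with probability
#' `plogis(intercept + x'beta)`. The follow-up registry copies the baseline,
#' advances the reporting year, removes the obstetric department codes and
#' birth procedures of closed sites, and scales surviving sites' births by
#' the configured growth factor.
#'
#' @param registry baseline registry (as from [place_hospitals()]).
#' @param covariates data.frame with one row per registry site: `site_id`,
#'   `live_births`, `has_pediatrics`, `density_category`, `fertility_rate`,
#'   `min_interfacility_time`, `ownership`, `teaching`. Missing values are an
#'   error naming the site and field.
#' @param model a [true_model()]; if its intercept is `NULL` it is calibrated
#'   to `target_rate` on these covariates.
#' @param seed integer seed for the Bernoulli draws.
#' @param target_rate marginal closure rate used when calibrating.
#' @param births_growth growth factor for surviving sites' births.
#' @param followup_year reporting year of the produced registry.
#' @return list with `closed` (named logical), `probability` (named numeric),
#'   `model` (with the intercept actually used) and `followup` (registry
#'   data.frame).
#' @export
simulate_closures <- function(registry, covariates, model, seed,
                              target_rate = 0.1026,
                              births_growth = 1.2521,
                              followup_year = NULL) {
  stopifnot(is.data.frame(registry), is.data.frame(covariates),
            inherits(model, "true_model"))
  if (missing(seed) || is.null(seed)) stop("an integer seed is mandatory")
  covariates <- covariates[match(registry$site_id, covariates$site_id), , drop = FALSE]
  if (anyNA(covariates$site_id)) {
    stop("covariates missing for site ",
         registry$site_id[which(is.na(covariates$site_id))[1L]])
  }
  if (is.null(model$intercept)) {
    model <- calibrate_intercept(model, covariates, target_rate)
  }
  eta <- model$intercept + true_model_eta(model, covariates)
  p <- stats::plogis(eta)
  set.seed(as.integer(seed))
  closed <- stats::runif(nrow(registry)) < p
  names(closed) <- registry$site_id
  names(p) <- registry$site_id

  followup <- registry
  if (is.null(followup_year)) followup_year <- registry$year[1L] + 5L
  followup$year <- followup_year
  grown <- pmax(1L, as.integer(round(covariates$live_births * births_growth)))
  followup$procedures <- births_to_procedures(grown)
  # closed sites lose the obstetric department codes and their birth codes
  followup$departments[closed] <- vapply(
    strsplit(followup$departments[closed], ";", fixed = TRUE),
    function(dd) paste(setdiff(dd, c("2400", "2425", "2500")), collapse = ";"),
    ""
  )
  followup$procedures[closed] <- ""
  list(closed = closed, probability = p, model = model, followup = followup)
}

#' Generate a complete synthetic region
#'
#' Convenience orchestrator: network, area attributes, baseline registry,
#' competition covariate, and (optionally) simulated closures with the
#' matching follow-up registry.
#'
#' @param config a [region_config()].
#' @param model a [true_model()], or `NULL` to skip the closure simulation.
#' @param target_rate marginal closure rate for intercept calibration.
#' @return list with `network`, `areas`, `baseline`, `covariates`, and (when
#'   a model is given) `closed`, `probability`, `model`, `followup`.
#' @export
simulate_region <- function(config, model = true_model(), target_rate = 0.1026) {
  net <- generate_network(config)
  areas <- generate_areas(net, config)
  baseline <- place_hospitals(net, config, areas)
  cov <- registry_covariates(baseline, net, areas)
  out <- list(network = net, areas = areas$areas, node_area = areas$node_area,
              baseline = baseline, covariates = cov)
  if (!is.null(model)) {
    sim <- simulate_closures(baseline, cov, model, seed = config$seed + 3L,
                             target_rate = target_rate,
                             births_growth = config$births_growth,
                             followup_year = config$years[2])
    out <- c(out, sim)
  }
  out
}

#' Covariate table for a registry
#'
#' Derives the model covariates of every registry site: live births from the
#' coded procedures, pediatrics from department codes, density and fertility
#' by area linkage, and the minimal inter-facility travel time over the
#' network.
#'
#' @param registry registry data.frame.
#' @param network a [road_network()].
#' @param areas result of [generate_areas()] or a bare `areas` data.frame
#'   (then `postal_area` linkage uses the registry's own column).
#' @return data.frame of covariates, one row per site.
#' @export
registry_covariates <- function(registry, network, areas) {
  ar <- if (is.data.frame(areas)) areas else areas$areas
  j <- match(registry$postal_area, ar$postal_area)
  if (anyNA(j)) {
    stop("no area attributes for postal_area ",
         registry$postal_area[which(is.na(j))[1L]])
  }
  mt <- min_interfacility_time(network, registry$node_id)
  data.frame(
    site_id = registry$site_id,
    live_births = count_live_births(registry$procedures),
    has_pediatrics = has_department(registry$departments, "1000"),
    ownership = registry$ownership,
    teaching = registry$teaching,
    density_raw = ar$density_raw[j],
    density_category = ar$density_category[j],
    fertility_rate = ar$fertility_rate[j],
    min_interfacility_time = mt,
    stringsAsFactors = FALSE
  )
}
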