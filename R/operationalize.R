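#' Procedure codes documenting live births
#'
#' The five codes of the "measures accompanying birth" subsection whose
#' counts operationalize the annual number of live births at a site.
#' @export
LIVE_BIRTH_CODES <- c("9-262", "9-262.0", "9-262.1", "9-262.x", "9-262.y")

#' Department codes identifying an obstetrics/gynecology department
#' @export
OBSTETRIC_DEPARTMENT_CODES <- c("2400", "2425", "2500")

#' Department code identifying a pediatrics department
#' @export
PEDIATRICS_DEPARTMENT_CODE <- "1000"

# Parse one "code:count;code:count" string into a named integer vector.
# Malformed entries are dropped with a warning rather than failing the row.
parse_procedures <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(integer(0))
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(trimws(parts))]
  out <- integer(0)
  for (p in parts) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1L]]
    cnt <- if (length(kv) == 2L) suppressWarnings(as.integer(kv[2L])) else NA_integer_
    if (length(kv) != 2L || is.na(cnt) || cnt < 0L) {
      warning("malformed procedure entry '", p, "' excluded", call. = FALSE)
      next
    }
    code <- trimws(kv[1L])
    out[code] <- sum(out[code], cnt, na.rm = TRUE)
  }
  out
}

#' Count documented live births from coded procedures
#'
#' Sums the procedure counts over exactly the five live-birth codes
#' ([LIVE_BIRTH_CODES]); any other code contributes nothing. Malformed
#' entries raise a warning and are excluded.
#'
#' @param procedures character vector of `"code:count;code:count"` strings
#'   (one element per hospital record), or a registry data.frame with a
#'   `procedures` column.
#' @return integer vector of live-birth counts.
#' @examples
#' count_live_births("9-262.0:300;9-262.1:100")  # 400
#' count_live_births("5-740:250")                # caesarean code: 0
#' @export
count_live_births <- function(procedures) {
  if (is.data.frame(procedures)) procedures <- procedures$procedures
  vapply(as.character(procedures), function(s) {
    cnt <- parse_procedures(s)
    as.integer(sum(cnt[names(cnt) %in% LIVE_BIRTH_CODES]))
  }, integer(1), USE.NAMES = FALSE)
}

#' Does a record's department list contain any of the given codes?
#'
#' @param departments character vector of `;`-separated specialty codes.
#' @param codes codes to look for (e.g. [PEDIATRICS_DEPARTMENT_CODE]).
#' @return logical vector.
#' @export
has_department <- function(departments, codes) {
  vapply(strsplit(as.character(departments), ";", fixed = TRUE),
         function(dd) any(trimws(dd) %in% codes), logical(1))
}

#' Identify obstetric hospital sites
#'
#' Keeps exactly the registry records that (i) carry an obstetrics and/or
#' gynecology department code, (ii) have at least one documented live birth,
#' and (iii) are acute-care facilities (day-care and rehabilitation
#' facilities never offer obstetric services and are dropped when a
#' `facility_type` column is present).
#'
#' @param registry registry data.frame (see [read_registry()]).
#' @param obstetric_codes department codes counting as obstetrics/gynecology.
#' @return The filtered registry (possibly empty).
#' @export
identify_obstetric_sites <- function(registry,
                                     obstetric_codes = OBSTETRIC_DEPARTMENT_CODES) {
  if (nrow(registry) == 0L) return(registry)
  keep <- has_department(registry$departments, obstetric_codes) &
    count_live_births(registry$procedures) >= 1L
  if (!is.null(registry$facility_type)) {
    keep <- keep & !(registry$facility_type %in% c("day_care", "rehabilitation"))
  }
  registry[keep, , drop = FALSE]
}

#' Build the two-year closure cohort
#'
#' Links the baseline and follow-up obstetric registries by site id and
#' produces one row per baseline obstetric site with the closure outcome:
#' `closed_by_followup` is `TRUE` iff the site is absent from the follow-up
#' obstetric set, and `total_hospital_closure` additionally requires that the
#' whole site vanished from the follow-up registry (or carries the
#' whole-closure flag there). When a network and area table are supplied the
#' model covariates (density, fertility, minimal inter-facility travel time)
#' are populated as well.
#'
#' @param baseline,followup registries already filtered by
#'   [identify_obstetric_sites()]. `followup_full` may carry the unfiltered
#'   follow-up registry used to detect whole-hospital closures; it defaults
#'   to `followup`.
#' @param followup_full unfiltered follow-up registry (all facility records).
#' @param network optional [road_network()] for the competition covariate.
#' @param areas optional area attribute table (`postal_area`, `density_raw`,
#'   `density_category`, `fertility_rate`) or [generate_areas()] result.
#' @return data.frame of class `closure_cohort`.
#' @export
build_closure_cohort <- function(baseline, followup, followup_full = followup,
                                 network = NULL, areas = NULL) {
  for (nm in c("baseline", "followup")) {
    reg <- get(nm)
    if (anyDuplicated(reg$site_id)) {
      stop("duplicate site_id within the ", nm, " year: ",
           reg$site_id[duplicated(reg$site_id)][1L])
    }
  }
  closed <- !(baseline$site_id %in% followup$site_id)
  present_full <- baseline$site_id %in% followup_full$site_id
  flagged <- rep(FALSE, nrow(baseline))
  if (!is.null(followup_full$whole_hospital_closed)) {
    j <- match(baseline$site_id, followup_full$site_id)
    flagged[!is.na(j)] <- isTRUE_vec(followup_full$whole_hospital_closed[j[!is.na(j)]])
  }
  total <- closed & (!present_full | flagged)

  out <- data.frame(
    site_id = baseline$site_id,
    live_births = count_live_births(baseline$procedures),
    has_pediatrics = has_department(baseline$departments, PEDIATRICS_DEPARTMENT_CODE),
    ownership = baseline$ownership,
    teaching = baseline$teaching,
    density_raw = NA_real_,
    density_category = NA_character_,
    fertility_rate = NA_real_,
    fertility_category = NA_character_,
    min_interfacility_time = NA_real_,
    closed_by_followup = closed,
    total_hospital_closure = total,
    stringsAsFactors = FALSE
  )
  if (!is.null(areas)) {
    ar <- if (is.data.frame(areas)) areas else areas$areas
    j <- match(baseline$postal_area, ar$postal_area)
    if (anyNA(j)) {
      stop("no area attributes for postal_area ",
           baseline$postal_area[which(is.na(j))[1L]])
    }
    out$density_raw <- ar$density_raw[j]
    out$density_category <- as.character(categorize_density(out$density_raw))
    out$fertility_rate <- ar$fertility_rate[j]
    out$fertility_category <- as.character(categorize_fertility(out$fertility_rate))
  }
  if (!is.null(network)) {
    out$min_interfacility_time <- min_interfacility_time(network, baseline$node_id)
  }
  class(out) <- c("closure_cohort", "data.frame")
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Apply the regression-sample exclusions
#'
#' Removes university hospital sites (no closures occur there, so they carry
#' no information on the closure process) and sites whose entire hospital
#' closed (where factors beyond the obstetrics department drive the
#' outcome). Returns the remaining rows; the exclusion counts are attached
#' as attribute `exclusion_log`.
#'
#' @param cohort a [build_closure_cohort()] result.
#' @return the regression cohort with an `exclusion_log` attribute
#'   (data.frame: `rule`, `n_removed`, `n_remaining`).
#' @export
apply_exclusions <- function(cohort) {
  n0 <- nrow(cohort)
  uni <- cohort$teaching == "university"
  c1 <- cohort[!uni, , drop = FALSE]
  tot <- isTRUE_vec(c1$total_hospital_closure)
  c2 <- c1[!tot, , drop = FALSE]
  log <- data.frame(
    rule = c("university_hospital", "total_hospital_closure"),
    n_removed = c(sum(uni), sum(tot)),
    n_remaining = c(nrow(c1), nrow(c2))
  )
  if (nrow(c2) == 0L) warning("all cohort rows excluded; empty regression cohort")
  attr(c2, "exclusion_log") <- log
  c2
}

#' Categorize population density
#'
#' Three-tier classification of inhabitants per square kilometre: low
#' (<= 100), medium (> 100 and <= 1000), high (> 1000). The published rule
#' leaves 500--1000 unstated; here medium extends to 1000 so the three
#' categories partition the domain while the printed high cutoff (> 1000)
#' is retained.
#'
#' @param density_raw numeric, inhabitants/km^2 (>= 0).
#' @param cutpoints increasing pair `c(low_max, medium_max)`.
#' @return factor with levels `low`, `medium`, `high`.
#' @export
categorize_density <- function(density_raw, cutpoints = c(100, 1000)) {
  if (any(is.na(density_raw))) stop("density must not be missing")
  if (any(density_raw < 0)) stop("density must be non-negative")
  stopifnot(length(cutpoints) == 2L, cutpoints[1] < cutpoints[2])
  cut(density_raw, breaks = c(-Inf, cutpoints, Inf),
      labels = c("low", "medium", "high"), right = TRUE)
}

#' Categorize the total fertility rate
#'
#' Low (<= 1.3), medium (> 1.3 to <= 1.6), high (> 1.6) children per woman;
#' boundaries are closed on the left category exactly as printed. The
#' continuous rate is retained for modelling; the categories serve the
#' descriptive tables.
#'
#' @param rate numeric, children per woman (> 0).
#' @param cutpoints increasing pair `c(low_max, medium_max)`.
#' @return factor with levels `low`, `medium`, `high`.
#' @export
categorize_fertility <- function(rate, cutpoints = c(1.3, 1.6)) {
  if (any(is.na(rate))) stop("fertility rate must not be missing")
  if (any(rate <= 0)) stop("fertility rate must be positive")
  stopifnot(length(cutpoints) == 2L, cutpoints[1] < cutpoints[2])
  cut(rate, breaks = c(-Inf, cutpoints, Inf),
      labels = c("low", "medium", "high"), right = TRUE)
}

#' Minimal inter-facility travel time
#'
#' For every site, the shortest-path travel time over the road network to
#' the nearest *other* site: the competition covariate. With a single site
#' the value is `+Inf` (with a warning); a site unreachable from all others
#' also gets `+Inf` with a warning.
#'
#' @param network a [road_network()].
#' @param site_nodes character vector of network node ids, one per site.
#' @return numeric vector of minutes, one per site.
#' @export
min_interfacility_time <- function(network, site_nodes) {
  stopifnot(inherits(network, "road_network"))
  site_nodes <- as.character(site_nodes)
  unknown <- setdiff(site_nodes, network$nodes$node_id)
  if (length(unknown)) stop("site node(s) not in network: ", unknown[1L])
  n <- length(site_nodes)
  if (n < 2L) {
    warning("fewer than 2 sites: minimal inter-facility time is +Inf")
    return(rep(Inf, n))
  }
  d <- igraph::distances(network$graph, v = site_nodes, to = site_nodes,
                         weights = igraph::E(network$graph)$weight)
  diag(d) <- Inf
  # sites sharing a node compete at distance 0
  dup <- duplicated(site_nodes) | duplicated(site_nodes, fromLast = TRUE)
  res <- apply(d, 1L, min)
  res[dup] <- 0
  if (any(is.infinite(res))) {
    warning(sum(is.infinite(res)), " site(s) unreachable from every other site")
  }
  unname(res)
}

#' Descriptive comparison of two cohorts
#'
#' Medians/IQRs, means/min/max with Welch two-sample t-tests for continuous
#' variables; counts, percentages and Pearson chi-squared tests for
#' categorical variables. A chi-squared test with any zero expected cell
#' count is flagged unreliable.
#'
#' @param group1,group2 data.frames (e.g. baseline and follow-up cohorts).
#' @param continuous,categorical character vectors of column names present
#'   in both groups.
#' @param labels length-2 character, group labels.
#' @return object of class `descriptive_table`: list with elements
#'   `continuous` and `categorical`.
#' @export
descriptive_table <- function(group1, group2,
                              continuous = intersect(
                                c("live_births", "min_interfacility_time", "fertility_rate"),
                                names(group1)),
                              categorical = intersect(
                                c("ownership", "has_pediatrics", "teaching",
                                  "density_category", "fertility_category"),
                                names(group1)),
                              labels = c("group1", "group2")) {
  cont <- do.call(rbind, lapply(continuous, function(v) {
    x <- group1[[v]]; y <- group2[[v]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    tt <- if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
      list(statistic = 0, p.value = 1)  # identical degenerate samples
    } else {
      stats::t.test(x, y)
    }
    data.frame(variable = v,
               median1 = stats::median(x), q25_1 = unname(stats::quantile(x, .25)),
               q75_1 = unname(stats::quantile(x, .75)),
               mean1 = mean(x), min1 = min(x), max1 = max(x),
               median2 = stats::median(y), q25_2 = unname(stats::quantile(y, .25)),
               q75_2 = unname(stats::quantile(y, .75)),
               mean2 = mean(y), min2 = min(y), max2 = max(y),
               t = unname(tt$statistic), p = tt$p.value)
  }))
  cat_rows <- list(); cat_tests <- list()
  for (v in categorical) {
    f1 <- as.character(group1[[v]]); f2 <- as.character(group2[[v]])
    lev <- sort(unique(c(f1, f2)))
    t1 <- table(factor(f1, lev)); t2 <- table(factor(f2, lev))
    cat_rows[[v]] <- data.frame(
      variable = v, level = lev,
      n1 = as.integer(t1), pct1 = 100 * as.integer(t1) / max(1L, length(f1)),
      n2 = as.integer(t2), pct2 = 100 * as.integer(t2) / max(1L, length(f2))
    )
    m <- rbind(t1, t2)
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    cat_tests[[v]] <- data.frame(
      variable = v,
      chisq = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value,
      unreliable = any(ct$expected == 0) || anyNA(ct$expected)
    )
  }
  structure(list(
    labels = labels,
    continuous = cont,
    categorical = if (length(cat_rows)) do.call(rbind, cat_rows) else NULL,
    categorical_tests = if (length(cat_tests)) do.call(rbind, cat_tests) else NULL
  ), class = "descriptive_table")
}

#' @export
print.descriptive_table <- function(x, ...) {
  cat("Descriptive comparison:", x$labels[1], "vs", x$labels[2], "\n\n")
  if (!is.null(x$continuous)) {
    cat("Continuous (median [IQR], Welch t, p):\n")
    print(x$continuous[, c("variable", "median1", "median2", "t", "p")],
          row.names = FALSE, digits = 4)
  }
  if (!is.null(x$categorical_tests)) {
    cat("\nCategorical (Pearson chi-squared):\n")
    print(x$categorical_tests, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
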