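# Independent oracles and tiny fixture builders used across the suite.

# Build a road_network from a compact edge specification:
# edges = data.frame(from, to, time_min); coordinates are placed on a line
# (they are irrelevant for graph-based checks).
toy_network <- function(edges, nodes = NULL) {
  if (is.null(nodes)) {
    ids <- sort(unique(c(edges$from, edges$to)))
    nodes <- data.frame(node_id = ids, x = seq_along(ids), y = 0)
  }
  road_network(nodes, edges)
}

# Path graph n1 -(w1)- n2 -(w2)- n3 ... with the given weights.
path_network <- function(weights, ids = LETTERS[seq_len(length(weights) + 1L)]) {
  toy_network(data.frame(from = ids[-length(ids)], to = ids[-1L],
                         time_min = weights))
}

# Brute-force single/multi-source shortest times by enumerating all simple
# paths (exponential; for graphs with <= 8 nodes only).
brute_force_time_map <- function(network, facility_nodes) {
  ids <- network$nodes$node_id
  stopifnot(length(ids) <= 8L)
  adj <- lapply(ids, function(v) {
    e <- network$edges
    rbind(
      data.frame(nb = e$to[e$from == v], w = e$time_min[e$from == v]),
      data.frame(nb = e$from[e$to == v], w = e$time_min[e$to == v])
    )
  })
  names(adj) <- ids
  best <- stats::setNames(rep(Inf, length(ids)), ids)
  walk <- function(v, visited, cost) {
    if (cost < best[[v]]) best[[v]] <<- cost
    a <- adj[[v]]
    for (k in seq_len(nrow(a))) {
      if (!(a$nb[k] %in% visited)) {
        walk(a$nb[k], c(visited, a$nb[k]), cost + a$w[k])
      }
    }
  }
  for (s in unique(as.character(facility_nodes))) walk(s, s, 0)
  best
}

# Seeded random connected graph with <= 8 nodes (retry until connected via
# an independent union-find check, not the package's own connectivity test).
random_small_graph <- function(seed) {
  set.seed(seed)
  n <- sample(2:8, 1)
  ids <- paste0("v", seq_len(n))
  repeat {
    m <- sample(seq(n - 1L, n * (n - 1L) / 2L), 1)
    pairs <- t(utils::combn(n, 2))
    pick <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
    # union-find connectivity
    parent <- seq_len(n)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    for (k in seq_len(nrow(pick))) {
      ra <- find(pick[k, 1]); rb <- find(pick[k, 2])
      if (ra != rb) parent[ra] <- rb
    }
    if (length(unique(vapply(seq_len(n), find, 1L))) == 1L) break
  }
  toy_network(data.frame(from = ids[pick[, 1]], to = ids[pick[, 2]],
                         time_min = round(stats::runif(nrow(pick), 1, 60), 2)),
              nodes = data.frame(node_id = ids, x = seq_len(n), y = 0))
}

# Bernoulli log-likelihood of a logistic model.
logistic_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

# Exhaustive grid maximization of the logistic log-likelihood with
# progressive zooming: enumerate a full grid, re-center, shrink, repeat.
grid_logistic_mle <- function(X, y, lower = -6, upper = 6, steps = 25L,
                              zooms = 8L) {
  p <- ncol(X)
  centre <- rep(0, p)
  half <- (upper - lower) / 2
  for (z in seq_len(zooms)) {
    axes <- lapply(seq_len(p), function(j) {
      seq(centre[j] - half, centre[j] + half, length.out = steps)
    })
    grid <- as.matrix(expand.grid(axes))
    ll <- apply(grid, 1L, function(b) logistic_loglik(b, X, y))
    centre <- grid[which.max(ll), ]
    half <- half * 2.2 / steps  # next grid spans ~2 old steps
  }
  centre
}

# Direct Welch two-sample t statistic and p-value.
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# Pearson chi-squared for an r x c contingency table, no correction.
chisq_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(stat = stat, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Benjamini-Hochberg step-up by direct formula enumeration.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Small synthetic cohort for model-level tests: logistic closure in
# live births and pediatrics, everything else held fixed.
toy_cohort <- function(n, seed, beta0 = 2, beta_births = -0.004,
                       beta_ped = -1) {
  set.seed(seed)
  births <- round(stats::rlnorm(n, log(683), 0.68))
  ped <- stats::runif(n) < 0.4
  eta <- beta0 + beta_births * births + beta_ped * ped
  data.frame(
    site_id = paste0("s", seq_len(n)),
    live_births = births,
    has_pediatrics = ped,
    ownership = sample(c("private", "public", "nonprofit"), n, TRUE),
    teaching = sample(c("no", "yes"), n, TRUE),
    density_category = sample(c("low", "medium", "high"), n, TRUE,
                              prob = c(.2, .4, .4)),
    fertility_rate = round(stats::runif(n, 1.1, 1.9), 3),
    min_interfacility_time = round(stats::runif(n, 1, 60), 2),
    closed_by_followup = stats::runif(n) < stats::plogis(eta),
    total_hospital_closure = FALSE
  )
}

# One full synthetic-region replicate -> regression cohort (exercises the
# whole generation + operationalization chain).
replicate_cohort <- function(seed, n_sites = 702L) {
  sim <- simulate_region(region_config(n_sites = n_sites, seed = seed))
  b <- identify_obstetric_sites(sim$baseline)
  f <- identify_obstetric_sites(sim$followup)
  coh <- build_closure_cohort(b, f, followup_full = sim$followup,
                              network = sim$network, areas = sim$areas)
  apply_exclusions(coh)
}
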