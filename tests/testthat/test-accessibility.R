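test_that("multi-source travel times equal per-facility minima and oracles", {
  net <- path_network(c(10, 25))
  tm <- shortest_time_map(net, "A")
  expect_equal(unname(tm[c("A", "B", "C")]), c(0, 10, 35))
  expect_equal(unname(shortest_time_map(net, c("A", "C"))[["A"]]), 0)

  # 30-node random graph, 3 facilities: multi-source equals the minimum of
  # three independent single-source maps
  set.seed(24)
  cfg <- region_config(n_sites = 3, n_nodes = 30, seed = 24)
  big <- generate_network(cfg)
  fac <- sample(big$nodes$node_id, 3)
  multi <- shortest_time_map(big, fac)
  singles <- sapply(fac, function(f) shortest_time_map(big, f))
  expect_equal(unname(multi), unname(apply(singles, 1, min)), tolerance = 1e-12)

  expect_warning(allinf <- shortest_time_map(net, character(0)), "empty")
  expect_true(all(is.infinite(allinf)))
})

test_that("point sampling is uniform, seeded and snap-aware", {
  bb <- c(xmin = 0, xmax = 1, ymin = 0, ymax = 1)
  p <- sample_points(bb, 10000, seed = 25)
  expect_lt(abs(mean(p$x) - 0.5), 0.02)
  expect_lt(abs(mean(p$y) - 0.5), 0.02)
  expect_identical(p, sample_points(bb, 10000, seed = 25))
  expect_false(identical(p$x, sample_points(bb, 10000, seed = 26)$x))
  expect_equal(nrow(sample_points(bb, 1, seed = 1)), 1L)
  expect_error(sample_points(c(0, 0, 0, 1), 10, seed = 1), "degenerate")

  net <- path_network(c(5, 5))
  ps <- sample_points(c(xmin = 0, xmax = 4, ymin = -1, ymax = 1), 50, seed = 2,
                      network = net)
  expect_true(all(ps$node_id %in% net$nodes$node_id))
  expect_true(all(ps$snap_km >= 0))
})

test_that("time bands follow the 30/40-minute boundary convention", {
  expect_equal(as.character(classify_time(c(15, 29.99, 30, 35, 40, 40.01, Inf))),
               c("under30", "under30", "band30to40", "band30to40",
                 "band30to40", "over40", "over40"))
  expect_error(classify_time(-1), "non-negative")
})

test_that("scenario filters are inclusive on births and exact on pediatrics", {
  net <- path_network(c(5, 5, 5))
  fac <- facility_set(data.frame(
    site_id = c("s1", "s2", "s3", "s4"),
    node_id = c("A", "B", "C", "D"),
    live_births = c(600, 599, 1200, 80),
    has_pediatrics = c(FALSE, TRUE, TRUE, FALSE)
  ), net)
  kept <- apply_scenario(fac, scenario_spec("min600", min_live_births = 600))
  expect_setequal(kept$site_id, c("s1", "s3"))
  ped <- apply_scenario(fac, scenario_spec("ped", require_pediatrics = TRUE))
  expect_setequal(ped$site_id, c("s2", "s3"))
  expect_identical(apply_scenario(fac, scenario_spec("all")), fac)
  expect_warning(apply_scenario(fac, scenario_spec("none", min_live_births = 1e6)),
                 "no facility")
  expect_error(scenario_spec(""), "name")
  expect_error(facility_set(data.frame(site_id = "s", node_id = "ZZ",
                                       live_births = 1, has_pediatrics = TRUE),
                            net), "not in network")
})

test_that("coverage fractions are exact on constructed regions", {
  # everything within 10 minutes of the single facility
  near <- toy_network(data.frame(from = c("A", "A"), to = c("B", "C"),
                                 time_min = c(5, 8)),
                      nodes = data.frame(node_id = c("A", "B", "C"),
                                         x = c(0, 1, 2), y = 0))
  surf <- access_surface(near, data.frame(node_id = "A"), n = 500, seed = 3)
  rep1 <- coverage_report(surf)
  expect_equal(rep1$fraction[rep1$band == "under30"], 1)
  expect_equal(sum(rep1$fraction), 1, tolerance = 1e-9)

  # two far-apart clusters, facility in one: about half the mass is >40 min
  nodes <- data.frame(node_id = c("L1", "L2", "R1", "R2"),
                      x = c(0, 1, 100, 101), y = 0)
  edges <- data.frame(from = c("L1", "R1", "L2"), to = c("L2", "R2", "R1"),
                      time_min = c(1, 1, 200))
  twoc <- road_network(nodes, edges)
  surf2 <- access_surface(twoc, data.frame(node_id = "L1"), n = 4000, seed = 4,
                          bbox = c(xmin = -0.5, xmax = 101.5, ymin = -1, ymax = 1))
  rep2 <- coverage_report(surf2)
  f40 <- rep2$fraction[rep2$band == "over40"]
  se <- sqrt(0.5 * 0.5 / 4000)
  expect_lt(abs(f40 - 0.5), 3 * se + 0.015)  # snap split at the midpoint

  # self-comparison has zero deltas
  rep3 <- coverage_report(surf2, reference = surf2)
  expect_true(all(rep3$delta == 0))
  expect_error(coverage_report(surf2[0, ]), "no points")
})

test_that("restricting facilities never shortens any travel time", {
  cfg <- region_config(n_sites = 25, n_nodes = 150, seed = 27)
  net <- generate_network(cfg)
  set.seed(27)
  for (trial in 1:10) {
    fac <- sample(net$nodes$node_id, 25)
    sub <- sample(fac, sample(1:24, 1))
    t_full <- shortest_time_map(net, fac)
    t_sub <- shortest_time_map(net, sub)
    expect_true(all(t_sub >= t_full - 1e-9))
    b_full <- table(classify_time(t_full))
    b_sub <- table(classify_time(t_sub))
    expect_gte(b_sub[["over40"]], b_full[["over40"]])
  }
})

test_that("surfaces are reproducible and band-consistent", {
  cfg <- region_config(n_sites = 8, n_nodes = 80, seed = 28)
  net <- generate_network(cfg)
  fac <- data.frame(node_id = sample(net$nodes$node_id, 8))
  s1 <- access_surface(net, fac, n = 600, seed = 5)
  s2 <- access_surface(net, fac, n = 600, seed = 5)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_identical(as.character(s1$band),
                   as.character(classify_time(s1$min_time)))
  expect_true(all(s1$min_time >= 0))
})
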