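test_that("live births are counted from exactly the five birth codes", {
  expect_equal(count_live_births("9-262.0:300;9-262.1:100"), 400L)
  expect_equal(count_live_births("5-740:250"), 0L)  # caesarean code alone
  expect_equal(count_live_births("9-262:10;9-262.x:1;9-262.y:2"), 13L)
  expect_equal(count_live_births(c("", "9-262.0:5")), c(0L, 5L))
  expect_warning(v <- count_live_births("9-262.0:10;garbage;9-262.1:oops"),
                 "malformed")
  expect_equal(suppressWarnings(count_live_births("9-262.0:10;garbage")), 10L)
})

test_that("obstetric sites require a department code and documented births", {
  reg <- data.frame(
    site_id = c("a", "b", "c", "d", "e"),
    year = 2014L,
    departments = c("2400", "2500", "1000", "2500;2400", "2400"),
    procedures = c("", "9-262.0:10", "9-262.0:5", "9-262.1:3", "5-740:9"),
    ownership = "public", teaching = "no",
    facility_type = c("acute", "acute", "acute", "day_care", "acute"),
    stringsAsFactors = FALSE
  )
  kept <- identify_obstetric_sites(reg)
  # a: gynecology dept but no births; c: pediatrics-only with mis-coded
  # births; d: day-care; e: no birth codes -> only b remains
  expect_equal(kept$site_id, "b")
  expect_equal(nrow(identify_obstetric_sites(reg[0, ])), 0L)
})

test_that("the closure cohort links years and flags whole-hospital closures", {
  base <- data.frame(
    site_id = c("a", "b", "c"), year = 2014L,
    departments = "2500;2400", procedures = "9-262.0:100",
    ownership = "public", teaching = "no", stringsAsFactors = FALSE
  )
  fu_same <- base; fu_same$year <- 2019L
  coh0 <- build_closure_cohort(base, fu_same)
  expect_equal(sum(coh0$closed_by_followup), 0L)

  # b keeps only non-obstetric departments; c vanishes entirely
  fu <- fu_same[1:2, ]
  fu$departments[2] <- "1000"
  fu$procedures[2] <- ""
  fu_obst <- identify_obstetric_sites(fu)
  coh <- build_closure_cohort(base, fu_obst, followup_full = fu)
  expect_equal(coh$closed_by_followup, c(FALSE, TRUE, TRUE))
  expect_equal(coh$total_hospital_closure, c(FALSE, FALSE, TRUE))

  # flagged whole closure still present in the registry
  fu2 <- fu_same
  fu2$departments[3] <- ""
  fu2$procedures[3] <- ""
  fu2$whole_hospital_closed <- c(FALSE, FALSE, TRUE)
  coh2 <- build_closure_cohort(base, identify_obstetric_sites(fu2),
                               followup_full = fu2)
  expect_true(coh2$closed_by_followup[3] && coh2$total_hospital_closure[3])

  dup <- rbind(base, base[1, ])
  expect_error(build_closure_cohort(dup, fu_same), "duplicate site_id")
})

test_that("exclusions remove university hospitals and whole-hospital closures", {
  coh <- toy_cohort(100, seed = 8)
  coh$teaching[1:7] <- "university"
  coh$total_hospital_closure[8:12] <- TRUE
  coh$closed_by_followup[8:12] <- TRUE
  out <- apply_exclusions(coh)
  expect_equal(nrow(out), 88L)
  log <- attr(out, "exclusion_log")
  expect_equal(log$n_removed, c(7L, 5L))
  expect_equal(log$n_remaining, c(93L, 88L))

  expect_identical(nrow(apply_exclusions(toy_cohort(50, seed = 9))), 50L)

  all_uni <- toy_cohort(10, seed = 10)
  all_uni$teaching <- "university"
  expect_warning(empty <- apply_exclusions(all_uni), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("density and fertility categorizers follow the printed cutpoints", {
  expect_equal(as.character(categorize_density(c(50, 100, 300, 750, 1000, 1500))),
               c("low", "low", "medium", "medium", "medium", "high"))
  expect_error(categorize_density(-1), "non-negative")
  expect_equal(as.character(categorize_fertility(c(1.3, 1.45, 1.6, 1.61))),
               c("low", "medium", "medium", "high"))
  expect_error(categorize_fertility(0), "positive")
  # categories always agree with the raw value under the cutpoints
  set.seed(2)
  d <- runif(500, 0, 3000)
  cat3 <- categorize_density(d)
  expect_true(all((d <= 100) == (cat3 == "low")))
  expect_true(all((d > 1000) == (cat3 == "high")))
})

test_that("minimal inter-facility time matches brute-force enumeration", {
  net2 <- path_network(12)
  expect_equal(min_interfacility_time(net2, c("A", "B")), c(12, 12))

  net3 <- path_network(c(5, 7))
  expect_equal(min_interfacility_time(net3, c("A", "B", "C")), c(5, 5, 7))

  expect_warning(one <- min_interfacility_time(net3, "A"), "fewer than 2")
  expect_identical(one, Inf)

  # random small graphs vs exhaustive simple-path enumeration
  for (s in 1:10) {
    net <- random_small_graph(300 + s)
    ids <- net$nodes$node_id
    sites <- sample(ids, min(3, length(ids)))
    if (length(sites) < 2) next
    got <- min_interfacility_time(net, sites)
    want <- vapply(seq_along(sites), function(i) {
      bf <- brute_force_time_map(net, sites[-i])
      unname(bf[sites[i]])
    }, 0)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("descriptive tables reproduce the Welch and chi-squared oracles", {
  g <- toy_cohort(60, seed = 11)
  tab0 <- descriptive_table(g, g, continuous = "live_births",
                            categorical = "ownership")
  expect_equal(tab0$continuous$t, 0)
  expect_equal(tab0$continuous$p, 1)
  expect_equal(tab0$categorical_tests$chisq, 0, tolerance = 1e-12)
  expect_equal(tab0$categorical_tests$p, 1)

  set.seed(12)
  a <- g; b <- toy_cohort(55, seed = 13)
  tab <- descriptive_table(a, b, continuous = "live_births",
                           categorical = "ownership")
  wo <- welch_oracle(a$live_births, b$live_births)
  expect_equal(tab$continuous$t, wo$t, tolerance = 1e-6)
  expect_equal(tab$continuous$p, wo$p, tolerance = 1e-6)
  m <- rbind(table(factor(a$ownership)), table(factor(b$ownership)))
  co <- chisq_oracle(m)
  expect_equal(tab$categorical_tests$chisq, co$stat, tolerance = 1e-6)
  expect_equal(tab$categorical_tests$p, co$p, tolerance = 1e-6)

  x <- c(1.1, 2.3, 3.1, 4.0, 5.2); y <- c(2.0, 2.2, 2.9, 6.1, 7.3)
  ga <- data.frame(v = x); gb <- data.frame(v = y)
  t5 <- descriptive_table(ga, gb, continuous = "v", categorical = character(0))
  w5 <- welch_oracle(x, y)
  expect_equal(t5$continuous$t, w5$t, tolerance = 1e-6)
})

test_that("operationalization is deterministic end to end", {
  fx <- synthetic_quality_reports()
  run <- function() {
    b <- identify_obstetric_sites(fx$baseline)
    f <- identify_obstetric_sites(fx$followup)
    apply_exclusions(build_closure_cohort(b, f, followup_full = fx$followup,
                                          areas = fx$areas))
  }
  expect_identical(run(), run())
})
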