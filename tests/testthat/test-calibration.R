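test_that("averted costs back-solve from two net-savings horizons", {
  bs <- backsolve_averted_costs(44.5, 61.5, 241.5)
  expect_equal(bs$averted_short, 176.6667, tolerance = 1e-4)
  expect_equal(bs$averted_long, 236.3333, tolerance = 1e-4)
  net3 <- accrued_net_savings(bs$averted_short, bs$averted_long,
                              44.5)[["year3"]]
  expect_equal(net3, 161.7667, tolerance = 1e-4)
  # unit short-term averted cost, no long-term, no intervention cost
  bs0 <- backsolve_averted_costs(0, 0.6, 0.95)
  expect_equal(bs0$averted_short, 1)
  expect_equal(bs0$averted_long, 0)
  # degenerate schedule rows make the system singular
  sch <- accrual_schedule(list(year1 = c(0.5, 0.5), year10 = c(0.5, 0.5),
                               lifetime = c(1, 1)))
  expect_error(backsolve_averted_costs(1, 2, 3, sch), "singular")
  expect_warning(backsolve_averted_costs(10, -20, 5), "negative")
})

test_that("back-solve inverts the forward accrual map exactly", {
  set.seed(11)
  for (i in 1:50) {
    S <- runif(1, 1, 500); L <- runif(1, 0, 500); C <- runif(1, 0, 200)
    net <- accrued_net_savings(S, L, C)
    bs <- backsolve_averted_costs(C, net[["year1"]], net[["year10"]])
    expect_equal(bs$averted_short, S)
    expect_equal(bs$averted_long, L)
  }
})

test_that("condition back-solve reproduces its burden targets exactly", {
  cond <- backsolve_condition("dep-like", rr = 1.37,
                              excess_qalys_short = 24831,
                              excess_qalys_long = 43807,
                              excess_cost_short = 954e6,
                              excess_cost_long = 1277e6,
                              baseline_prevalence = 0.10)
  b <- compute_added_burden(cond)
  expect_equal(b$excess_qalys_short, 24831)
  expect_equal(b$excess_qalys_long_discounted, 43807)
  expect_equal(b$excess_cost_short, 954e6)
  expect_equal(b$excess_cost_long_discounted, 1277e6)
  # identity holds for arbitrary positive target tuples
  cond2 <- backsolve_condition("oud-like", rr = 1.63,
                               excess_qalys_short = 3239,
                               excess_qalys_long = 24877,
                               excess_cost_short = 166e6,
                               excess_cost_long = 385e6,
                               cost_per_episode = 79551)
  b2 <- compute_added_burden(cond2)
  expect_equal(b2$excess_qalys_short, 3239)
  expect_equal(b2$excess_qalys_long_discounted, 24877)
  expect_error(backsolve_condition("bad", rr = 1.0,
                                   excess_qalys_short = 1,
                                   excess_cost_short = 1,
                                   baseline_prevalence = 0.1),
               "rr > 1")
})

test_that("bundled scenarios reproduce every published target within 0.5%", {
  for (nm in names(bundled())) {
    sc <- bundled()[[nm]]
    res <- run_scenario(sc)
    b <- res$burden; iv <- res$intervention; t <- sc$targets
    got <- c(b$excess_qalys_short, b$excess_qalys_long_discounted,
             b$excess_cost_short, b$excess_cost_long_discounted,
             iv$qalys_gained_total, iv$intervention_cost_total,
             iv$net_savings_by_horizon[["year1"]],
             iv$net_savings_by_horizon[["year3"]],
             iv$net_savings_by_horizon[["year10"]])
    want <- unlist(t[c("excess_qalys_short", "excess_qalys_long",
                       "excess_cost_short", "excess_cost_long",
                       "qalys_gained", "intervention_cost",
                       "net1", "net3", "net10")])
    expect_lt(max(rel_dev(got, want)), 0.005)
  }
})

test_that("bundled scenarios encode their structural assumptions", {
  sc <- bundled()
  expect_setequal(names(sc), c("depression", "ipv", "homelessness",
                               "alcohol", "oud", "stroke"))
  expect_equal(sc$homelessness$condition$severity_multiplier, 0.25)
  expect_equal(sc$stroke$intervention$coverage, 1.0)
  expect_equal(sc$stroke$condition$long_term$cost_per_episode, 0)
  expect_equal(sc$stroke$condition$long_term$qaly_loss_per_episode, 0)
  for (nm in setdiff(names(sc), "stroke"))
    expect_equal(sc[[nm]]$intervention$coverage, 0.20, info = nm)
  # all conditions discount long-term outcomes at 3% over a 10-year lag
  for (nm in names(sc)) {
    expect_equal(sc[[nm]]$condition$discount_rate, 0.03, info = nm)
    expect_equal(sc[[nm]]$condition$long_term_lag_years, 10, info = nm)
  }
})

test_that("the random scenario generator is seeded and domain-respecting", {
  expect_equal(random_scenario(99), random_scenario(99))
  expect_false(identical(random_scenario(1)$condition,
                         random_scenario(2)$condition))
  for (seed in 1:30) {
    sc <- random_scenario(seed)
    cond <- sc$condition; iv <- sc$intervention
    expect_true(cond$baseline_prevalence > 0 && cond$baseline_prevalence < 1)
    expect_true(cond$rr_pandemic > 1)
    expect_lte(cond$baseline_prevalence * cond$rr_pandemic, 1)
    expect_true(iv$efficacy >= 0.05 && iv$efficacy <= 0.8)
    expect_true(iv$coverage > 0 && iv$coverage <= 1)
  }
  # generator does not disturb the caller's RNG stream
  set.seed(123); a <- runif(1)
  set.seed(123); invisible(random_scenario(5)); b <- runif(1)
  expect_identical(a, b)
})

test_that("a generated scenario with zero efficacy costs exactly its program cost", {
  sc <- random_scenario(7)
  sc$intervention$efficacy <- 0
  net <- run_scenario(sc)$intervention$net_savings_by_horizon
  expect_true(all(net ==
    -run_scenario(sc)$intervention$intervention_cost_total))
})
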