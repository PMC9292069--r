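test_that("degenerate distributions return their point value", {
  d <- param_distribution("x", "point", value = 1.37)
  expect_true(all(sample_distribution(d, 100) == 1.37))
  du <- param_distribution("x", "uniform", low = 3, high = 3)
  expect_true(all(sample_distribution(du, 50) == 3))
  expect_error(param_distribution("x", "uniform", low = 2, high = 1),
               "inverted")
  expect_error(param_distribution("x", "lognormal-from-95CI",
                                  low = -1, high = 2), "positive")
  expect_error(param_distribution("x", "beta-from-95CI",
                                  low = 0.5, high = 1.2), "\\(0, 1\\)")
  expect_error(param_distribution("x", "pert", low = 0, high = 1, mode = 2),
               "mode")
})

test_that("CI-matched families recover their bounds empirically", {
  set.seed(314)
  n <- 2e5
  dln <- param_distribution("x", "lognormal-from-95CI",
                            low = 1.20, high = 2.56)
  q <- quantile(sample_distribution(dln, n), c(0.025, 0.975), type = 7)
  expect_equal(unname(q), c(1.20, 2.56), tolerance = 0.02)

  db <- param_distribution("x", "beta-from-95CI", low = 0.2, high = 0.3)
  q <- quantile(sample_distribution(db, n), c(0.025, 0.975), type = 7)
  expect_equal(unname(q), c(0.2, 0.3), tolerance = 0.02)

  dg <- param_distribution("x", "gamma-from-95CI", low = 800, high = 1200)
  q <- quantile(sample_distribution(dg, n), c(0.025, 0.975), type = 7)
  expect_equal(unname(q), c(800, 1200), tolerance = 0.02)
})

test_that("a median-anchored lognormal keeps the base case at its median", {
  d <- param_distribution("x", "lognormal-from-95CI",
                          low = 1.20, high = 2.56, median = 1.37)
  set.seed(42)
  expect_equal(unname(quantile(sample_distribution(d, 2e5), 0.5, type = 7)),
               1.37, tolerance = 0.02)
})

test_that("sampling respects the target parameter's domain", {
  d <- param_distribution("x", "uniform", low = -1, high = 1,
                          domain = c(0, 1))
  set.seed(5)
  x <- sample_distribution(d, 1000)
  expect_true(all(x >= 0 & x <= 1))
})

test_that("an all-point-mass PSA equals the deterministic pipeline exactly", {
  sc <- bundled()$depression
  det <- run_scenario(sc)
  cfg <- psa_config(list(
    param_distribution("condition.rr_pandemic", "point",
                       value = sc$condition$rr_pandemic),
    param_distribution("intervention.efficacy", "point",
                       value = sc$intervention$efficacy)),
    n_draws = 10, seed = 1)
  p <- run_psa(sc, cfg)
  expect_true(all(p$summary$upper == p$summary$lower))
  expect_equal(p$summary$mean[p$summary$output == "qalys_gained_total"],
               det$intervention$qalys_gained_total)
  expect_equal(p$summary$mean[p$summary$output == "net_savings_lifetime"],
               unname(det$intervention$net_savings_by_horizon[["lifetime"]]))
})

test_that("identical seed and configuration give identical PSA summaries", {
  sc <- bundled()$alcohol
  cfg <- psa_config(default_psa_distributions(sc), n_draws = 300, seed = 2024)
  a <- run_psa(sc, cfg)
  b <- run_psa(sc, cfg)
  expect_identical(a$summary, b$summary)
  c2 <- run_psa(sc, psa_config(default_psa_distributions(sc),
                               n_draws = 300, seed = 2025))
  expect_false(identical(a$summary, c2$summary))
})

test_that("PSA mean of a linear output matches the deterministic run at the
           distribution mean", {
  sc <- toy_scenario(efficacy = 0.2)
  det <- run_scenario(sc)$intervention$qalys_gained_total
  cfg <- psa_config(list(
    param_distribution("intervention.efficacy", "uniform",
                       low = 0.1, high = 0.3)),
    n_draws = 4000, seed = 9)
  p <- run_psa(sc, cfg)
  expect_equal(p$summary$mean[p$summary$output == "qalys_gained_total"],
               det, tolerance = 0.02)
})

test_that("PSA summaries are internally coherent and draws are retained on
           request", {
  sc <- bundled()$oud
  cfg <- psa_config(default_psa_distributions(sc), n_draws = 200, seed = 3,
                    keep_draws = TRUE)
  p <- run_psa(sc, cfg)
  expect_true(all(p$summary$lower <= p$summary$mean &
                    p$summary$mean <= p$summary$upper))
  expect_equal(dim(p$draws), c(200, 5))
  expect_equal(colMeans(p$draws), setNames(p$summary$mean, p$summary$output))
})

test_that("implausible parameter distributions trip the rejection guard", {
  sc <- bundled()$depression  # baseline ~0.18, so rr = 10 is implausible
  cfg <- psa_config(list(
    param_distribution("condition.rr_pandemic", "point", value = 10)),
    n_draws = 20, seed = 1)
  expect_error(run_psa(sc, cfg), "rejection")
})

test_that("one-way DSA at the base value reproduces the base run", {
  sc <- bundled()$homelessness
  base <- run_scenario(sc)
  tab <- one_way_dsa(sc, "condition.rr_pandemic",
                     sc$condition$rr_pandemic)
  expect_equal(tab$qalys_gained, base$intervention$qalys_gained_total)
  expect_equal(tab$net_savings_lifetime,
               unname(base$intervention$net_savings_by_horizon[["lifetime"]]))
  expect_error(one_way_dsa(sc, "condition.not_a_field", 1), "unresolvable")
})

test_that("a monotone efficacy sweep yields monotone QALYs gained", {
  sc <- toy_scenario()
  tab <- one_way_dsa(sc, "intervention.efficacy", seq(0, 1, by = 0.1))
  expect_true(all(diff(tab$qalys_gained) > 0))
  expect_true(all(diff(tab$net_savings_lifetime) > 0))
})
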