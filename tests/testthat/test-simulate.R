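test_that("site generation respects bounds and the seed contract", {
  sim <- simulate_sites(true_model(seed = 3), n_sites = 12)
  d <- sim$sites
  expect_equal(nrow(d), 12)
  pars <- sim$model$parameters
  for (j in seq_len(nrow(pars))) {
    v <- d[[pars$parameter[j]]]
    expect_true(all(v >= pars$low[j] & v <= pars$high[j]))
  }
  expect_true(all(d$abundance >= 1))
  expect_true(all(d$abundance == round(d$abundance)))
  # reasonable emulation of the observed abundance variation
  expect_true(all(d$abundance < 1e6))
  # same seed, byte-identical output
  expect_identical(d, simulate_sites(true_model(seed = 3), n_sites = 12)$sites)
  expect_false(identical(
    d, simulate_sites(true_model(seed = 4), n_sites = 12)$sites))
})

test_that("noiseless sites at the optimum yield the abundance scale", {
  # pin every parameter to a sliver around its optimum: expected abundance
  # collapses to the abundance scale (rounded)
  pars <- data.frame(parameter = "depth", low = 54.49999, high = 54.50001,
                     mu_true = 54.5, sigma_true = 19)
  m <- true_model(parameters = pars, dispersion = 0,
                  abundance_scale = 5000, seed = 2)
  d <- simulate_sites(m, n_sites = 10)$sites
  expect_true(all(d$abundance == 5000))
})

test_that("generator rejects invalid inputs naming the parameter", {
  expect_error(simulate_sites(true_model(), n_sites = 1), "n_sites")
  expect_error(
    true_model(parameters = data.frame(parameter = c("a", "depth"),
                                       low = c(0, 10), high = c(1, 10))),
    "depth")
  expect_error(true_model(gamma = 0), "gamma")
  expect_error(true_model(n_species = 1), "at least 2")
})

test_that("seasonal replicate mode emits one row per visit", {
  sim <- simulate_sites(true_model(seed = 9), n_sites = 5, seasons = 4)
  expect_equal(nrow(sim$sites), 20)
  expect_equal(sort(unique(sim$sites$season)), 1:4)
  expect_equal(sum(sim$sites$site == "W01"), 4)
})

test_that("community composition encodes the specialization-dominance trade-off", {
  m <- true_model(gamma = 1, n_species = 4, seed = 1)
  # h = 0: uniform expected composition, Shannon = ln 4
  c0 <- simulate_community(0, m, n_individuals = 4000, noise = FALSE)
  expect_equal(unname(c0[1, ]), rep(1000L, 4))
  expect_equal(shannon(c0[1, ]), log(4))
  # h = 1: specialist at its cap, Shannon near zero
  c1 <- simulate_community(1, m, n_individuals = 10000, noise = FALSE)
  expect_gt(c1[1, 1], 9900)
  expect_lt(shannon(c1[1, ]), 0.05)
  # expected-composition Shannon strictly decreasing on an h grid
  h <- seq(0.1, 0.9, by = 0.1)
  cg <- simulate_community(h, true_model(gamma = 2, seed = 1),
                           n_individuals = 1e6, noise = FALSE)
  H <- shannon(cg)
  expect_true(all(diff(H) < 0))
  expect_error(simulate_community(numeric(0), m), "empty")
  expect_error(simulate_community(c(0.5, 1.2), m), "\\[0, 1\\]")
})

test_that("community draws are seeded and integer-valued", {
  m <- true_model(seed = 6)
  a <- simulate_community(c(0.2, 0.8), m)
  b <- simulate_community(c(0.2, 0.8), m)
  expect_identical(a, b)
  expect_true(all(a == round(a)))
  expect_equal(unname(rowSums(a)), c(1000, 1000))
})

test_that("grid generation honors the protected fraction and spans classes", {
  g <- simulate_grids(100, 100, pa_fraction = 0.5, seed = 1)
  frac <- mean(g$protected$data == 1)
  expect_gte(frac, 0.48); expect_lte(frac, 0.52)
  expect_true(all(g$suitability$data >= 0 & g$suitability$data <= 1))
  expect_true(all(g$density$data >= 0))
  # histogram spans all four equal-interval suitability classes
  cls <- equal_interval_classes(g$suitability$data)
  expect_true(all(cls$counts > 0))
  g2 <- simulate_grids(100, 100, pa_fraction = 0.5, seed = 1)
  expect_identical(g, g2)
  expect_error(simulate_grids(10, 10, pa_fraction = 1.5), "pa_fraction")
})

test_that("prediction-set separation controls discrimination", {
  # exchangeable null: AUC near 0.5 at n = 10,000
  s0 <- simulate_prediction_sets(10000, 10000, separation = 0, seed = 2)
  expect_equal(auc(s0$presence, s0$background), 0.5, tolerance = 0.02)
  # disjoint supports: AUC exactly 1
  s2 <- simulate_prediction_sets(500, 500, separation = 2, seed = 2)
  expect_equal(auc(s2$presence, s2$background), 1.0)
  # separation 1: positive calibration ratio by direct evaluation
  s1 <- simulate_prediction_sets(1000, 1000, separation = 1, seed = 2)
  expect_gt(calibration_ratio(s1$presence, s1$background), 0)
  expect_true(all(c(s1$presence, s1$background) >= 0 &
                    c(s1$presence, s1$background) <= 1))
  expect_error(simulate_prediction_sets(0, 10), ">= 1")
})
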