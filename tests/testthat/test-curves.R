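test_that("weighted Gaussian fit reproduces hand-computed weighted moments", {
  cv <- weighted_gaussian_fit(c(1, 2, 3), c(1, 1, 1), "p")
  expect_equal(cv$mu, 2)
  expect_equal(cv$sigma, sqrt(2 / 3))
  expect_equal(c(cv$low, cv$high), c(1, 3))

  # values {0,4}, weights {1,3}: mu = 3, sigma = sqrt((1*9 + 3*1)/4)
  cv2 <- weighted_gaussian_fit(c(0, 4), c(1, 3), "p")
  expect_equal(cv2$mu, 3)
  expect_equal(cv2$sigma, sqrt(3))

  # reliability-weight variant uses the unbiased denominator
  cv3 <- weighted_gaussian_fit(c(0, 4), c(1, 3), "p", type = "reliability")
  expect_equal(cv3$sigma, sqrt(12 / (4 - 10 / 4)))
})

test_that("degenerate fits are explicit errors, not silent zeros", {
  expect_error(weighted_gaussian_fit(c(5, 5, 5), c(1, 2, 3), "p"),
               "degenerate niche")
  expect_error(weighted_gaussian_fit(c(1, 2, 3), c(0, 0, 0), "p"),
               "weights are zero")
  # zero-weight sites do not rescue a degenerate positively weighted set
  expect_error(weighted_gaussian_fit(c(1, 5, 5), c(0, 1, 2), "p"),
               "degenerate niche")
})

test_that("Gaussian suitability matches the closed form and clamps", {
  cv <- weighted_gaussian_fit(c(1, 2, 3), c(1, 1, 1), "p")
  expect_equal(gaussian_suitability(cv$mu, cv), 1.0)
  expect_equal(gaussian_suitability(cv$mu + cv$sigma, cv), exp(-1 / 2))
  expect_equal(gaussian_suitability(cv$mu - 2 * cv$sigma, cv, clamp = FALSE),
               exp(-2))
  # clamping clips to the observed bound before evaluating
  expect_equal(gaussian_suitability(100, cv, clamp = TRUE),
               gaussian_suitability(cv$high, cv))
  expect_error(gaussian_suitability(NaN, cv), "non-finite")
})

test_that("suitability is symmetric about mu and decays monotonically", {
  cv <- weighted_gaussian_fit(c(2, 5, 9, 14), c(3, 8, 5, 1), "p")
  d <- seq(0.1, 3, by = 0.3)
  expect_equal(gaussian_suitability(cv$mu + d, cv, clamp = FALSE),
               gaussian_suitability(cv$mu - d, cv, clamp = FALSE))
  s <- gaussian_suitability(cv$mu + d, cv, clamp = FALSE)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s <= 1))
})

test_that("optimal range is mu +/- sigma clipped to observed bounds", {
  # dissolved-oxygen published optimum back-solves to mu 7.54, sigma 1.12
  cv <- structure(list(parameter = "do", mu = 7.54, sigma = 1.12,
                       low = 5.8, high = 10.4, type = "frequency"),
                  class = "suitability_curve")
  expect_equal(unname(optimal_range(cv)), c(6.42, 8.66))
  cv2 <- structure(list(parameter = "p", mu = 0, sigma = 1,
                        low = -0.5, high = 10, type = "frequency"),
                   class = "suitability_curve")
  expect_equal(unname(optimal_range(cv2)), c(-0.5, 1))
})

test_that("noiseless fits recover the generating optimum and the weighted-moment limit", {
  # temperature: a narrow field range relative to its mean, so the n = 200
  # weighted-mean sampling error sits well inside the 1% recovery tolerance
  # (wide-range parameters like depth carry ~2% sampling error at this n)
  pars <- data.frame(parameter = "temperature", low = 28, high = 31.6)
  model <- true_model(parameters = pars, dispersion = 0, seed = 11)
  sim <- simulate_sites(model, n_sites = 200)$sites
  fit <- weighted_gaussian_fit(sim$temperature, sim$abundance, "temperature")

  # brute-force weighted-moment oracle: naive accumulation loop
  sw <- sx <- 0
  for (i in seq_len(200)) {
    sw <- sw + sim$abundance[i]
    sx <- sx + sim$abundance[i] * sim$temperature[i]
  }
  mu_bf <- sx / sw
  ss <- 0
  for (i in seq_len(200))
    ss <- ss + sim$abundance[i] * (sim$temperature[i] - mu_bf)^2
  expect_equal(fit$mu, mu_bf, tolerance = 1e-12)
  expect_equal(fit$sigma, sqrt(ss / sw), tolerance = 1e-12)

  mu_t <- model$parameters$mu_true
  sig_t <- model$parameters$sigma_true
  expect_lt(abs(fit$mu - mu_t) / mu_t, 0.01)

  # analytic limit: uniform sampling on the bounds weighted by the Gaussian
  # response concentrates near the optimum, shrinking sigma below sigma_true
  z <- seq(-1.5, 1.5, length.out = 20001)  # (bounds span 3 sigma_true)
  w <- exp(-z^2 / 2)
  var_lim <- sum(w * z^2) / sum(w)
  sigma_lim <- sig_t * sqrt(var_lim)
  expect_lt(abs(fit$sigma - sigma_lim) / sigma_lim, 0.10)
  expect_lt(sigma_lim, sig_t)
})

test_that("texture score normalizes Cosby conductivity over the site set", {
  sand <- c(0.80, 0.50, 0.30, 0.50)
  silt <- c(0.15, 0.30, 0.40, 0.30)
  clay <- c(0.05, 0.20, 0.30, 0.20)
  sc <- texture_score(sand, silt, clay)
  # sandiest/least-clay site has the highest conductivity -> score 1
  expect_equal(sc[1], 1)
  # min-conductivity site gets the floor
  expect_equal(sc[3], 1e-3)
  # identical compositions score identically
  expect_equal(sc[2], sc[4])
  expect_true(all(sc >= 1e-3 & sc <= 1))

  expect_error(texture_score(0.5, 0.3, 0.2), "at least two sites")
  expect_error(texture_score(c(0.9, 0.5), c(0.3, 0.3), c(0.2, 0.2)),
               "deviates from 1")
  expect_error(texture_score(c(1.2, 0.5), c(-0.2, 0.3), c(0, 0.2)),
               "\\[0, 1\\]")
})

test_that("curves serialize to CSV and read back losslessly", {
  sites <- make_sites()
  fit <- hsi_fit(sites)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curves(fit, path)
  back <- read_curves(path)
  expect_identical(names(back), names(fit$curves))
  for (p in names(back)) {
    expect_identical(back[[p]]$mu, fit$curves[[p]]$mu)
    expect_identical(back[[p]]$sigma, fit$curves[[p]]$sigma)
  }
})
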