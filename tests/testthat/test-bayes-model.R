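test_that("the sensory-noise power law evaluates correctly", {
  expect_equal(sigma_r(5:30, 0.7, 0), rep(0.7, 26))
  expect_equal(sigma_r(16, 0.15, 0.5), 0.6, tolerance = 1e-12)
  # Weber regime: sigma_R / N constant
  expect_equal(sigma_r(5:30, 0.2, 1) / (5:30), rep(0.2, 26))
  expect_error(sigma_r(0.5, 1, 1), "at least 1")
  expect_error(sigma_r(10, -1, 1), "positive")
})

test_that("the posterior mean interpolates between stimulus and prior", {
  # coincident centres: no shrinkage whatever the widths
  expect_equal(posterior_mean(15, 15, 5, 3), 15)
  expect_equal(posterior_mean(15, 15, 0.1, 100), 15)
  # hand-evaluated precision weighting with the (15, 5) prior, sigma_R = 3
  expect_equal(posterior_mean(5, 15, 5, 3), 260 / 34, tolerance = 1e-12)
  expect_equal(posterior_mean(30, 15, 5, 3), 885 / 34, tolerance = 1e-12)
  # noiseless likelihood dominates; infinite-noise limit approaches prior
  expect_equal(posterior_mean(30, 15, 5, 0), 30)
  expect_lt(abs(posterior_mean(30, 15, 5, 1e8) - 15), 1e-6)
  expect_error(posterior_mean(10, 15, 0, 0), "undefined")
})

test_that("shrinkage towards the prior is monotone in sensory noise", {
  sigmas <- seq(0.5, 20, by = 0.5)
  for (n in c(5, 25, 30)) {
    r <- posterior_mean(rep(n, length(sigmas)), 15, 5, sigmas)
    expect_true(all(diff(abs(r - 15)) < 0))          # ever closer to prior
    expect_true(all(r > min(n, 15) & r < max(n, 15)))  # strictly between
  }
})

test_that("the sensory weight behaves as a convex blending coefficient", {
  expect_equal(likelihood_weight(15, 0, 5), 1)
  expect_gt(likelihood_weight(15, 0.2, 1e9), 1 - 1e-12)
  expect_equal(likelihood_weight(15, 0.2, 5), 25 / 34, tolerance = 1e-12)
  w <- likelihood_weight(seq(1, 30), 0.2, 5)
  expect_true(all(w > 0 & w <= 1))
  expect_true(all(diff(w) < 0))  # non-increasing in magnitude
})

test_that("weight and posterior-mean formulations agree to machine precision", {
  set.seed(1234)
  for (i in 1:10000) {
    x <- runif(1, 1, 40)
    wf <- runif(1, 0, 1)
    psd <- runif(1, 0.5, 30)
    pm <- runif(1, 1, 35)
    w <- likelihood_weight(x, wf, psd)
    expect_equal(posterior_mean(x, pm, psd, x * wf), w * x + (1 - w) * pm,
                 tolerance = 1e-12)
  }
})

test_that("predicted mappings are compressive, ordered and bounded", {
  obs <- bayes_observer(15, 5, 0.58, 0.5, 0)
  mp <- predict_mapping(obs, 5:30)
  expect_true(all(diff(mp$predicted_response) > 0))   # strictly increasing
  expect_gt(mp$predicted_response[1], 5)              # small N overestimated
  expect_lt(mp$predicted_response[26], 30)            # large N underestimated
  expect_equal(predict_mapping(obs, 15)$predicted_response, 15)
  # flat prior: identity mapping
  flat <- predict_mapping(bayes_observer(15, 1e9, 0.58, 0.5, 0), 5:30)
  expect_equal(flat$predicted_response, as.numeric(5:30), tolerance = 1e-9)
  # monotonicity over random observers in the task's parameter ranges
  # (sigma_R must grow sub-quadratically in N; sub-linear growth with a
  # moderate prior keeps the mapping strictly increasing)
  set.seed(55)
  for (i in 1:50) {
    o <- bayes_observer(runif(1, 10, 20), runif(1, 3, 20),
                        runif(1, 0.05, 1.2), runif(1, 0, 0.7), 0)
    expect_true(all(diff(predict_mapping(o, 5:30)$predicted_response) > 0))
  }
})

test_that("the prior width is recovered from its own mapping", {
  obs <- bayes_observer(15, 5, 0.5, 0.5, 0)
  mp <- predict_mapping(obs, 5:30)
  dat <- data.frame(numerosity = 5:30, mean_response = mp$predicted_response)
  pf <- fit_prior(dat, list(noise_k = 0.5, noise_exponent = 0.5))
  expect_lt(abs(pf$prior_sd - 5), 0.25)
  expect_gt(pf$r_squared, 0.999)
})

test_that("a 0.01-resolution grid confirms the prior-width optimum", {
  obs <- bayes_observer(15, 7, 0.6, 0.5, 0)
  mp <- predict_mapping(obs, 5:30)
  # perturb slightly so the optimum is not trivially exact
  set.seed(66)
  dat <- data.frame(numerosity = 5:30,
                    mean_response = mp$predicted_response + rnorm(26, 0, 0.1))
  spec <- list(noise_k = 0.6, noise_exponent = 0.5)
  pf <- fit_prior(dat, spec, prior_sd_bounds = c(0.5, 50))
  grid <- seq(0.5, 50, by = 0.01)
  r2 <- vapply(grid, function(s) {
    pred <- posterior_mean(5:30, 15, s, sigma_r(5:30, 0.6, 0.5))
    1 - sum((dat$mean_response - pred)^2) /
      sum((dat$mean_response - mean(dat$mean_response))^2)
  }, numeric(1))
  expect_lt(abs(pf$prior_sd - grid[which.max(r2)]), 0.011)
})

test_that("identity data push the prior width to its bound; degenerate data fail", {
  dat <- data.frame(numerosity = 5:30, mean_response = as.numeric(5:30))
  pf <- fit_prior(dat, list(noise_k = 0.5, noise_exponent = 0.5),
                  prior_sd_bounds = c(0.5, 1000))
  expect_gt(pf$prior_sd, 900)
  expect_gt(pf$r_squared, 0.9999)
  flat <- data.frame(numerosity = 5:30, mean_response = 15)
  expect_error(fit_prior(flat, list(noise_k = 0.5, noise_exponent = 0.5)),
               "Degenerate")
})

test_that("prior-mean modes resolve as documented", {
  obs <- bayes_observer(15, 5, 0.5, 0.5, 0)
  dat <- data.frame(numerosity = 5:30,
                    mean_response = predict_mapping(obs, 5:30)$predicted_response)
  spec <- list(noise_k = 0.5, noise_exponent = 0.5)
  expect_equal(fit_prior(dat, spec, "fixed_value", prior_mean = 15)$prior_mean, 15)
  expect_equal(fit_prior(dat, spec, "fixed_midpoint")$prior_mean, 17.5)
  free <- fit_prior(dat, spec, "free")
  expect_lt(abs(free$prior_mean - 15), 0.5)
})

test_that("simulated non-linearity decreases with sensory noise", {
  # noiseless limit: linear mapping, vanishing internal noise
  tiny <- nonlinearity_vs_noise_curve(prior_sd = 17, wf_grid = 0.01,
                                      n_sim = 200, seed = 1)
  expect_lt(abs(tiny$exponent - 1), 0.05)
  expect_lt(tiny$internal_noise, 0.02)
  for (seed in 1:3) {
    cv <- nonlinearity_vs_noise_curve(prior_sd = 17, n_sim = 100, seed = seed)
    expect_lte(cor(cv$wf, cv$exponent, method = "spearman"), 0)
    expect_true(all(cv$exponent[cv$wf >= 0.1] < 1))
    expect_true(all(diff(cv$internal_noise) > 0))
  }
})
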