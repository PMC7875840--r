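test_that("the scalar-variability likelihood matches hand-computed values", {
  # single trial at the mode with predicted SD 1: -log(1/sqrt(2*pi))
  expect_equal(negloglik_linear(0, 1, 0.1, 10, 10), 0.5 * log(2 * pi),
               tolerance = 1e-12)
  # doubling the residual at fixed SD quadruples the quadratic term
  base <- negloglik_linear(0, 1, 0.1, 10, 10)
  d1 <- negloglik_linear(0, 1, 0.1, 10, 11) - base
  d2 <- negloglik_linear(0, 1, 0.1, 10, 12) - base
  expect_equal(d2, 4 * d1, tolerance = 1e-10)
  # permutation invariance of the sum
  set.seed(1)
  N <- sample(5:30, 40, TRUE); R <- N + rnorm(40)
  p <- sample(40)
  expect_equal(negloglik_linear(1, 0.9, 0.2, N, R),
               negloglik_linear(1, 0.9, 0.2, N[p], R[p]))
  expect_equal(negloglik_power(1.2, 0.8, 0.2, N, R),
               negloglik_power(1.2, 0.8, 0.2, N[p], R[p]))
})

test_that("invalid predicted SDs yield a flagged finite penalty", {
  v <- negloglik_linear(-20, 1, 0.1, c(5, 10), c(5, 10))  # negative means
  expect_true(is.finite(v))
  expect_gte(as.numeric(v), 1e10)
  expect_true(isTRUE(attr(v, "penalized")))
})

test_that("noiseless linear data are recovered essentially exactly", {
  set.seed(2)
  N <- rep(5:30, 3)
  R <- 2 + 0.9 * N + rnorm(length(N), 0, 1e-6)
  f <- fit_linear_mle(N, R)
  expect_true(f$converged)
  expect_equal(f$intercept, 2, tolerance = 1e-3)
  expect_equal(f$slope, 0.9, tolerance = 1e-3)
})

test_that("power fits recover identity and known-exponent generators", {
  set.seed(3)
  N <- rep(5:30, 3)
  f_id <- fit_power_mle(N, N + rnorm(length(N), 0, 1e-6))
  expect_equal(f_id$scale, 1, tolerance = 1e-3)
  expect_equal(f_id$exponent, 1, tolerance = 1e-3)
  # R = 3 * N^0.5 with 1% multiplicative noise
  N2 <- rep(5:30, 20)
  mu <- 3 * N2^0.5
  f_sqrt <- suppressWarnings(
    fit_power_mle(N2, mu * (1 + rnorm(length(N2), 0, 0.01))))
  expect_lt(abs(f_sqrt$exponent - 0.5), 0.03)
  expect_error(fit_power_mle(1:5, 1:5), "at least 10")
  expect_error(fit_power_mle(rep(10, 20), rnorm(20, 10)), "3 distinct")
})

test_that("central-tendency observers always yield compressive exponents", {
  for (seed in 1:20) {
    set.seed(seed)
    N <- sample(5:30, 520, TRUE)
    sR <- sigma_r(N, 0.58, 0.5)
    R <- pmin(pmax(posterior_mean(N, 15, 5, sR) + rnorm(520, 0, sR), 1), 35)
    f <- fit_power_mle(N, R, n_starts = 3)
    expect_lt(f$exponent, 1)
  }
})

test_that("flat-prior Weber-noise data fit as linear (exponent near 1)", {
  # noise shape matches the model's scalar variability, so the MLE is
  # correctly specified and the identity mapping is recovered
  set.seed(11)
  obs <- default_observers(prior_sd = 1e9,
                           noise_k = c(VSL = 0.15, IS = 0.15, ID = 0.15),
                           noise_exponent = 1, response_jitter_sd = 0)
  d <- session_design(n_sessions = 1L, trials_per_session = 2000L,
                      n_training = 0L)
  tr <- simulate_session(d, obs)
  f <- fit_power_mle(tr$numerosity, tr$response)
  expect_lt(abs(f$exponent - 1), 0.02)
})

test_that("SD-vs-numerosity power fits recover exact and flat inputs", {
  exact <- fit_sd_power(data.frame(numerosity = 5:30, sd = 0.5 * sqrt(5:30)))
  expect_equal(exact$exponent, 0.5, tolerance = 1e-10)
  expect_equal(exact$scale, 0.5, tolerance = 1e-10)
  flat <- fit_sd_power(data.frame(numerosity = 5:30, sd = 2))
  expect_equal(flat$exponent, 0, tolerance = 1e-10)
  expect_warning(
    fit_sd_power(data.frame(numerosity = 5:10, sd = c(0, 1, 2, 1, 2, 1))),
    "excluded")
  expect_error(fit_sd_power(data.frame(numerosity = 5:6, sd = c(1, 2))),
               "at least 3")
})

test_that("pooled SD scaling recovers the generator's exponent across seeds", {
  for (seed in 1:20) {
    tr <- simulate_experiment(n_subjects = 15, subject_sd = 0,
                              seed = 1000 + seed)
    cl <- clean_trials(tr)$trials
    agg <- aggregate(response ~ numerosity, cl, sd)
    names(agg)[2] <- "sd"
    f <- fit_sd_power(agg)
    expect_lt(abs(f$exponent - 0.5), 0.07)
  }
})

test_that("noise summaries match hand computations and scale homogeneously", {
  tr <- data.frame(subject_id = "s01", condition = "VSL",
                   numerosity = c(10, 10), response = c(9, 11))
  ns <- compute_noise_summary(tr)
  expect_equal(ns$summary$internal_noise, sd(c(0.9, 1.1)), tolerance = 1e-12)
  # perfect responses: zero internal noise
  tr2 <- data.frame(subject_id = "s01", condition = "VSL",
                    numerosity = rep(5:10, each = 2),
                    response = rep(5:10, each = 2))
  expect_equal(compute_noise_summary(tr2)$summary$internal_noise, 0)
  # scaling all responses by c scales internal noise by c
  tr3 <- tr2; tr3$response <- tr3$response + rep(c(-1, 1), 6)
  base <- compute_noise_summary(tr3)$summary$internal_noise
  tr4 <- tr3; tr4$response <- 3 * tr4$response
  expect_equal(compute_noise_summary(tr4)$summary$internal_noise, 3 * base,
               tolerance = 1e-12)
  # under-filled conditions are omitted with a warning
  tr5 <- rbind(tr2, data.frame(subject_id = "s01", condition = "ID",
                               numerosity = 10, response = 10))
  expect_warning(ns5 <- compute_noise_summary(tr5), "omitted")
  expect_false("ID" %in% ns5$summary$condition)
})

test_that("sigma_n tracks the coefficient of variation across noise levels", {
  set.seed(21)
  ks <- seq(0.05, 0.3, length.out = 10)
  sn <- cv <- numeric(10)
  for (i in seq_along(ks)) {
    N <- sample(5:30, 520, TRUE)
    R <- N + rnorm(520, 0, ks[i] * N)     # Weber-scaled noise
    f <- fit_linear_mle(N, R, n_starts = 5)
    sn[i] <- f$sigma_n
    tab <- aggregate(R, list(N = N), sd)
    cv[i] <- mean(tab$x / tab$N)
  }
  expect_gt(cor(sn, cv), 0.9)
})
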