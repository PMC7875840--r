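test_that("the end-to-end pipeline populates all three conditions", {
  rep1 <- run_pipeline(list(seed = 42L))
  pc <- rep1$per_condition
  expect_setequal(pc$condition, c("VSL", "IS", "ID"))
  expect_true(all(pc$converged))
  expect_true(all(pc$sigma_n > 0))
  expect_true(all(pc$power_exponent > 0 & pc$power_exponent < 1.5))
  expect_true(all(is.finite(pc$mean_rt)))
  expect_length(rep1$bayes, 3)
  expect_true(all(vapply(rep1$bayes, function(b) b$r_squared, 1) > 0))
  expect_true(rep1$nonlinearity_noise_correlation$defined)
  # attention ordering propagates end to end in this realisation
  expect_true(pc$power_exponent[pc$condition == "VSL"] >
                pc$power_exponent[pc$condition == "ID"])
  expect_true(pc$sigma_n[pc$condition == "VSL"] <
                pc$sigma_n[pc$condition == "ID"])
})

test_that("report regeneration from the same seed is byte-identical", {
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  cfg <- list(seed = 7L, simulation = list(n_subjects = 4L))
  run_pipeline(cfg, out = f1)
  run_pipeline(cfg, out = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("every reported number is recomputable from persisted trials", {
  cfg <- list(seed = 9L, simulation = list(n_subjects = 4L))
  set.seed(9L)
  trials <- simulate_experiment(n_subjects = 4L, seed = 9L)
  csv <- tempfile(fileext = ".csv")
  write_trials(trials, csv)
  rep1 <- run_pipeline(cfg)
  # independent recomputation from the round-tripped CSV
  back <- read_trials(csv)
  cl <- clean_trials(back)
  set.seed(9L)  # not used by cleaning; fits are start-point deterministic
  pc <- condition_summaries(cl$trials, n_starts = 10)
  expect_equal(pc$cv, rep1$per_condition$cv, tolerance = 1e-10)
  expect_equal(pc$internal_noise, rep1$per_condition$internal_noise,
               tolerance = 1e-10)
  expect_equal(pc$sigma_n, rep1$per_condition$sigma_n, tolerance = 1e-3)
  expect_equal(pc$power_exponent, rep1$per_condition$power_exponent,
               tolerance = 1e-3)
})

test_that("single-condition input yields a single-condition report", {
  trials <- simulate_experiment(n_subjects = 4L, seed = 11L)
  vsl <- trials[trials$condition == "VSL", ]
  rep1 <- run_pipeline(list(seed = 11L), trials = vsl)
  expect_equal(rep1$per_condition$condition, "VSL")
  expect_length(rep1$bayes, 1)
  expect_true(all(rep1$subject_fits$condition == "VSL"))
})

test_that("noise-free observers give linear mappings and an undefined correlation", {
  obs <- default_observers(noise_k = c(VSL = 1e-9, IS = 1e-9, ID = 1e-9),
                           response_jitter_sd = 0)
  trials <- simulate_experiment(n_subjects = 5L, observers = obs,
                                subject_sd = 0, sensory_scatter = FALSE,
                                seed = 13L)
  cl <- clean_trials(trials)$trials
  sf <- subject_power_fits(cl, n_starts = 2)
  expect_true(all(abs(sf$exponent - 1) < 1e-3))
  corr <- correlate_nonlinearity_noise(sf)
  expect_false(corr$defined)
  expect_true(is.na(corr$r))
})

test_that("the noise correlation behaves on collinear and permuted data", {
  d <- data.frame(exponent = 1 - seq(0.1, 0.5, length.out = 9),
                  internal_noise = seq(0.1, 0.5, length.out = 9))
  expect_equal(correlate_nonlinearity_noise(d)$r, 1, tolerance = 1e-12)
  # permutation null: correlation centred on zero
  set.seed(3)
  d2 <- data.frame(exponent = runif(12, 0.4, 1),
                   internal_noise = runif(12, 0.1, 0.5))
  rs <- replicate(200, {
    d2$internal_noise <- sample(d2$internal_noise)
    correlate_nonlinearity_noise(d2)$r
  })
  expect_lt(abs(mean(rs)), 0.1)
  expect_error(correlate_nonlinearity_noise(d[1:2, ]), "at least 3")
})

test_that("trial tables and configs round-trip through disk", {
  trials <- simulate_experiment(n_subjects = 1L, seed = 21L)
  csv <- tempfile(fileext = ".csv")
  write_trials(trials, csv)
  back <- read_trials(csv)
  expect_equal(back$response, trials$response)
  expect_equal(back$condition, trials$condition)
  expect_identical(back$is_training, trials$is_training)
  bad <- trials; bad$condition[1] <- "XX"
  write.csv(bad, csv, row.names = FALSE)
  expect_error(read_trials(csv), "Unknown condition")
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 5", "simulation:", "  n_subjects: 3"), yml)
  cfg <- read_config(yml)
  expect_equal(cfg$seed, 5)
  expect_equal(cfg$simulation$n_subjects, 3)
})

test_that("report plots build without error", {
  rep1 <- run_pipeline(list(seed = 31L, simulation = list(n_subjects = 3L)))
  expect_s3_class(plot_mapping(rep1), "ggplot")
  curve <- nonlinearity_vs_noise_curve(wf_grid = c(0.1, 0.3), n_sim = 100,
                                       seed = 1)
  expect_s3_class(plot_nonlinearity_noise(rep1, curve), "ggplot")
})
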