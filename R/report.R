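#' Per-condition response-model summaries
#'
#' For each cue-validity condition present in the (cleaned) trial table,
#' fits the linear scalar-variability model (yielding `sigma_n`) and the
#' power-function model (yielding the non-linearity exponent), and attaches
#' the coefficient of variation and internal noise from
#' [compute_noise_summary()].
#'
#' @param trials Cleaned trial data frame.
#' @param n_starts Optimisation starts per fit.
#' @return Data frame, one row per condition: `condition`, `n_trials`,
#'   `sigma_n`, `intercept`, `slope`, `power_scale`, `power_exponent`, `cv`,
#'   `internal_noise`, `converged`.
#' @export
condition_summaries <- function(trials, n_starts = 10) {
  noise <- compute_noise_summary(trials)
  rows <- lapply(intersect(conditions(), unique(trials$condition)), function(cc) {
    sub <- trials[trials$condition == cc, ]
    lin <- fit_linear_mle(sub$numerosity, sub$response, n_starts = n_starts)
    pow <- suppressWarnings(
      fit_power_mle(sub$numerosity, sub$response, n_starts = n_starts))
    ns <- noise$summary[noise$summary$condition == cc, ]
    data.frame(condition = cc, n_trials = nrow(sub),
               sigma_n = lin$sigma_n, intercept = lin$intercept,
               slope = lin$slope,
               power_scale = pow$scale, power_exponent = pow$exponent,
               cv = ns$cv, internal_noise = ns$internal_noise,
               converged = lin$converged && pow$converged)
  })
  do.call(rbind, rows)
}

#' Per-subject, per-condition power fits with internal noise
#'
#' Fits the power-function model separately for every subject x condition
#' cell with at least `min_trials` trials, pairing each fitted exponent with
#' that cell's internal noise (SD of response/numerosity). These pairs are
#' the points of the non-linearity-vs-noise analysis.
#'
#' @param trials Cleaned trial data frame.
#' @param min_trials Minimum trials per cell (default 30).
#' @param n_starts Optimisation starts per fit.
#' @return Data frame: `subject_id`, `condition`, `n_trials`, `exponent`,
#'   `internal_noise`, `converged`.
#' @export
subject_power_fits <- function(trials, min_trials = 30, n_starts = 3) {
  cells <- unique(trials[c("subject_id", "condition")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- trials[trials$subject_id == cells$subject_id[i] &
                    trials$condition == cells$condition[i], ]
    if (nrow(sub) < min_trials) return(NULL)
    pow <- suppressWarnings(
      fit_power_mle(sub$numerosity, sub$response, n_starts = n_starts))
    data.frame(subject_id = cells$subject_id[i],
               condition = cells$condition[i],
               n_trials = nrow(sub),
               exponent = pow$exponent,
               internal_noise = stats::sd(sub$response / sub$numerosity),
               converged = pow$converged)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("No subject x condition cell reached ", min_trials, " trials.")
  }
  out
}

#' Correlation between non-linearity and internal noise
#'
#' Pearson correlation, across subject x condition points, between internal
#' noise and the non-linearity index `1 - exponent`. The sign convention
#' makes a positive `r` mean "noisier observers have more compressed
#' number-line mappings", the direction predicted by the central-tendency
#' model. If either variable has (numerically) zero variance the
#' correlation is undefined and flagged as such rather than guessed.
#'
#' @param subject_fits Data frame with columns `exponent` and
#'   `internal_noise` (e.g. from [subject_power_fits()]); at least 3 rows.
#' @return List: `r` (Pearson correlation or `NA`), `n` (points used),
#'   `defined` (logical).
#' @export
correlate_nonlinearity_noise <- function(subject_fits) {
  stopifnot(all(c("exponent", "internal_noise") %in% names(subject_fits)))
  d <- subject_fits[is.finite(subject_fits$exponent) &
                      is.finite(subject_fits$internal_noise), ]
  if (nrow(d) < 3) stop("Need at least 3 (exponent, internal_noise) pairs.")
  x <- d$internal_noise
  y <- 1 - d$exponent
  tol <- 1e-8
  if (stats::sd(x) <= tol * max(1, mean(abs(x))) ||
      stats::sd(y) <= tol * max(1, mean(abs(y)))) {
    return(list(r = NA_real_, n = nrow(d), defined = FALSE))
  }
  list(r = stats::cor(x, y), n = nrow(d), defined = TRUE)
}

#' Default pipeline configuration
#'
#' The configuration mirrors the study conditions: 15 subjects, four
#' sessions of 150 trials with 20 training trials, 75/12.5/12.5%
#' cue-validity split, numerosities 5-30 on a 1-35 line; observers with a
#' (15, 5) prior and square-root noise scaling ordered VSL < IS < ID;
#' 2-SD per-subject-per-condition outlier removal; a 150-ms reaction-time
#' floor on the RT branch; and a Bayesian prior fit with the prior mean
#' fixed at 15 and per-condition sensory noise `sigma_R(N) = CV * N`.
#'
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulation = list(n_subjects = 15L, subject_sd = 0.25),
    design = list(),     # overrides for session_design()
    observers = list(),  # overrides for default_observers()
    cleaning = list(n_training = 20L, k_sd = 2, min_rt = 0.150),
    bayes = list(prior_mean = 15, prior_mean_mode = "fixed_value",
                 sigma_r_from = "cv"),
    fitting = list(n_starts = 10L, subject_n_starts = 3L,
                   min_trials_subject = 30L)
  )
}

merge_config <- function(config) {
  base <- default_config()
  for (nm in names(config)) {
    if (is.list(base[[nm]]) && is.list(config[[nm]])) {
      base[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      base[[nm]] <- config[[nm]]
    }
  }
  base
}

#' Run the full desk-scale analysis pipeline
#'
#' Orchestrates the end-to-end analysis: obtain trials (simulate the
#' configured experiment, or analyse a supplied table), apply the standard
#' preprocessing, fit per-condition response models, fit the pooled
#' SD-vs-numerosity power law, fit the central-tendency prior per condition,
#' fit per-subject power functions and correlate non-linearity with internal
#' noise, and summarise reaction times on the RT-filtered branch. The result
#' is deterministic given the configuration seed.
#'
#' @param config Configuration list (see [default_config()]); partial lists
#'   are merged over the defaults.
#' @param trials Optional trial data frame; when supplied, no simulation is
#'   run.
#' @param out Optional path; the report is written there as JSON with
#'   stable field ordering.
#' @param plots_dir Optional directory for diagnostic figures (mapping
#'   curves, SD scaling, non-linearity vs noise).
#' @return Object of class `study_report`.
#' @export
run_pipeline <- function(config = list(), trials = NULL, out = NULL,
                         plots_dir = NULL) {
  cfg <- merge_config(config)
  design <- do.call(session_design, cfg$design)
  observers <- do.call(default_observers, cfg$observers)

  if (is.null(trials)) {
    trials <- simulate_experiment(
      n_subjects = cfg$simulation$n_subjects,
      design = design, observers = observers,
      subject_sd = cfg$simulation$subject_sd,
      seed = cfg$seed
    )
  }

  cleaned <- clean_trials(trials,
                          n_training = cfg$cleaning$n_training,
                          k_sd = cfg$cleaning$k_sd)
  clean <- cleaned$trials

  per_condition <- condition_summaries(clean, n_starts = cfg$fitting$n_starts)

  noise <- compute_noise_summary(clean)
  pooled_sd <- stats::aggregate(response ~ numerosity, data = clean,
                                FUN = stats::sd)
  names(pooled_sd)[2] <- "sd"
  sd_power_pooled <- fit_sd_power(pooled_sd)

  # Central-tendency fits per condition, likelihood width from the CV
  # estimates (sigma_R = CV * N) unless configured otherwise.
  bayes <- lapply(per_condition$condition, function(cc) {
    sub <- clean[clean$condition == cc, ]
    means <- stats::aggregate(response ~ numerosity, data = sub, FUN = mean)
    names(means)[2] <- "mean_response"
    spec <- if (identical(cfg$bayes$sigma_r_from, "sd_power")) {
      list(noise_k = sd_power_pooled$scale,
           noise_exponent = sd_power_pooled$exponent)
    } else {
      list(noise_k = per_condition$cv[per_condition$condition == cc],
           noise_exponent = 1)
    }
    pf <- fit_prior(means, spec,
                    prior_mean_mode = cfg$bayes$prior_mean_mode,
                    prior_mean = cfg$bayes$prior_mean)
    list(condition = cc, prior_mean = pf$prior_mean, prior_sd = pf$prior_sd,
         r_squared = pf$r_squared, predicted = pf$predicted)
  })
  names(bayes) <- per_condition$condition

  subj <- subject_power_fits(clean,
                             min_trials = cfg$fitting$min_trials_subject,
                             n_starts = cfg$fitting$subject_n_starts)
  corr <- correlate_nonlinearity_noise(subj)

  rt_branch <- filter_rt(clean, cfg$cleaning$min_rt)
  cleaned$report$n_rt_dropped <- attr(rt_branch, "n_removed")
  rt_summary <- stats::aggregate(rt ~ condition, data = rt_branch,
                                 FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  rt_summary <- data.frame(condition = rt_summary$condition,
                           mean_rt = rt_summary$rt[, "mean"],
                           sd_rt = rt_summary$rt[, "sd"])
  rt_summary <- rt_summary[match(per_condition$condition, rt_summary$condition), ]
  per_condition$mean_rt <- rt_summary$mean_rt
  per_condition$sd_rt <- rt_summary$sd_rt

  report <- structure(
    list(schema_version = "1.0",
         seed = cfg$seed,
         cleaning = cleaned$report,
         per_condition = per_condition,
         sd_power_pooled = sd_power_pooled,
         bayes = bayes,
         subject_fits = subj,
         nonlinearity_noise_correlation = corr),
    class = "study_report"
  )

  if (!is.null(out)) write_report_json(report, out)
  if (!is.null(plots_dir)) save_report_plots(report, clean, plots_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Cued number-line estimation study report (seed ", x$seed, ")\n", sep = "")
  print(x$cleaning)
  cat("\nPer-condition summaries\n")
  print(x$per_condition[c("condition", "n_trials", "sigma_n",
                          "power_exponent", "cv", "internal_noise",
                          "mean_rt")], row.names = FALSE, digits = 4)
  cat(sprintf("\nPooled SD-vs-N power law: scale %.3f, exponent %.3f\n",
              x$sd_power_pooled$scale, x$sd_power_pooled$exponent))
  for (b in x$bayes) {
    cat(sprintf("Bayes fit %-3s: prior SD %6.2f, R-squared %.3f\n",
                b$condition, b$prior_sd, b$r_squared))
  }
  if (x$nonlinearity_noise_correlation$defined) {
    cat(sprintf("\nNon-linearity vs internal noise: r = %.3f (n = %d)\n",
                x$nonlinearity_noise_correlation$r,
                x$nonlinearity_noise_correlation$n))
  } else {
    cat("\nNon-linearity vs internal noise: undefined (zero variance)\n")
  }
  invisible(x)
}

#' Serialise a study report to JSON
#'
#' Fields are written in a fixed order with unboxed scalars so that
#' regenerating a report from the same inputs and seed yields a
#' byte-identical file.
#'
#' @param report A `study_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  payload <- list(
    schema_version = report$schema_version,
    seed = report$seed,
    cleaning = unclass(report$cleaning),
    per_condition = report$per_condition,
    sd_power_pooled = report$sd_power_pooled,
    bayes = lapply(report$bayes, function(b) {
      list(condition = b$condition, prior_mean = b$prior_mean,
           prior_sd = b$prior_sd, r_squared = b$r_squared,
           predicted = b$predicted)
    }),
    subject_fits = report$subject_fits,
    nonlinearity_noise_correlation = report$nonlinearity_noise_correlation
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}
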