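#' Describe the design of a cued-enumeration session
#'
#' A `session_design` captures the generative description of one experimental
#' session of the cued number-line task: how many trials are run, how trials
#' are split between the cue-validity conditions, which numerosities can be
#' shown, and the extent of the response line.
#'
#' The defaults mirror the standard design: four sessions of 150 trials, a
#' 75% / 12.5% / 12.5% split between valid same-location (VSL), invalid
#' same-object (IS) and invalid different-object (ID) trials, numerosities
#' drawn from 5..30, a response line spanning 1..35, and the first 20 trials
#' of each session treated as training.
#'
#' @param n_sessions Number of sessions per subject.
#' @param trials_per_session Trials in each session.
#' @param p_vsl,p_is,p_id Per-trial probabilities of the three cue-validity
#'   conditions. Must sum to 1. Because 75% of 150 is not an integer, trials
#'   are assigned to conditions i.i.d. with these probabilities rather than
#'   as exact within-session counts.
#' @param n_min,n_max Integer bounds of the numerosity range (inclusive).
#' @param line_min,line_max Extremes of the number line on which responses
#'   are given. Must bracket the numerosity range.
#' @param n_training Leading trials per session flagged as training and
#'   excluded by [drop_training()].
#'
#' @return An object of class `session_design`.
#' @seealso [simulate_session()], [simulate_experiment()]
#' @export
#' @examples
#' session_design()
session_design <- function(n_sessions = 4L,
                           trials_per_session = 150L,
                           p_vsl = 0.75, p_is = 0.125, p_id = 0.125,
                           n_min = 5L, n_max = 30L,
                           line_min = 1, line_max = 35,
                           n_training = 20L) {
  n_sessions <- as.integer(n_sessions)
  trials_per_session <- as.integer(trials_per_session)
  n_training <- as.integer(n_training)
  if (n_sessions < 1L) stop("`n_sessions` must be a positive integer.")
  if (trials_per_session < 1L) stop("`trials_per_session` must be a positive integer.")
  if (n_training < 0L) stop("`n_training` must be non-negative.")
  p <- c(p_vsl, p_is, p_id)
  if (any(p < 0) || any(p > 1)) stop("Condition probabilities must lie in [0, 1].")
  if (abs(sum(p) - 1) > 1e-8) {
    stop("Condition probabilities must sum to 1 (got ", format(sum(p)), ").")
  }
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  if (n_min < 1L) stop("`n_min` must be at least 1.")
  if (n_max <= n_min) stop("`n_max` must exceed `n_min`.")
  if (line_min > n_min || line_max < n_max) {
    stop("The number line [", line_min, ", ", line_max,
         "] must contain the numerosity range [", n_min, ", ", n_max, "].")
  }
  structure(
    list(n_sessions = n_sessions, trials_per_session = trials_per_session,
         p_vsl = p_vsl, p_is = p_is, p_id = p_id,
         n_min = n_min, n_max = n_max,
         line_min = line_min, line_max = line_max,
         n_training = n_training),
    class = "session_design"
  )
}

#' @export
print.session_design <- function(x, ...) {
  cat("Cued-enumeration session design\n")
  cat(sprintf("  %d session(s) x %d trials (%d training)\n",
              x$n_sessions, x$trials_per_session, x$n_training))
  cat(sprintf("  P(condition) VSL/IS/ID: %.3f / %.3f / %.3f\n",
              x$p_vsl, x$p_is, x$p_id))
  cat(sprintf("  numerosity %d..%d on a %g-%g line\n",
              x$n_min, x$n_max, x$line_min, x$line_max))
  invisible(x)
}

#' Parameters of the Bayesian central-tendency observer
#'
#' The observer combines a noisy sensory estimate of numerosity `N` with a
#' Gaussian prior over the stimulus range. The sensory (likelihood) standard
#' deviation scales with numerosity as `sigma_R(N) = noise_k * N^noise_exponent`
#' (see [sigma_r()]), and the predicted response is the posterior mean, a
#' precision-weighted average of `N` and the prior mean (see
#' [posterior_mean()]). `response_jitter_sd` is additional constant motor /
#' readout noise added when responses are simulated.
#'
#' @param prior_mean Centre of the Gaussian prior, in dots.
#' @param prior_sd Standard deviation of the prior; must be positive.
#' @param noise_k Coefficient of the sensory-noise power law; must be positive.
#' @param noise_exponent Exponent of the sensory-noise power law. 0 gives
#'   constant noise, 1 gives Weber-law (proportional) noise; number-line data
#'   are typically closest to square-root scaling (0.5).
#' @param response_jitter_sd Non-negative SD of constant motor noise on the
#'   simulated response.
#'
#' @return An object of class `bayes_observer`.
#' @export
#' @examples
#' bayes_observer(prior_mean = 15, prior_sd = 5, noise_k = 0.58)
bayes_observer <- function(prior_mean = 15, prior_sd = 5,
                           noise_k = 0.58, noise_exponent = 0.5,
                           response_jitter_sd = 0.5) {
  if (!is.finite(prior_mean)) stop("`prior_mean` must be finite.")
  if (!is.finite(prior_sd) || prior_sd <= 0) stop("`prior_sd` must be positive.")
  if (!is.finite(noise_k) || noise_k <= 0) stop("`noise_k` must be positive.")
  if (!is.finite(noise_exponent)) stop("`noise_exponent` must be finite.")
  if (!is.finite(response_jitter_sd) || response_jitter_sd < 0) {
    stop("`response_jitter_sd` must be non-negative.")
  }
  structure(
    list(prior_mean = prior_mean, prior_sd = prior_sd,
         noise_k = noise_k, noise_exponent = noise_exponent,
         response_jitter_sd = response_jitter_sd),
    class = "bayes_observer"
  )
}

#' @export
print.bayes_observer <- function(x, ...) {
  cat("Bayesian central-tendency observer\n")
  cat(sprintf("  prior: Normal(%g, %g)\n", x$prior_mean, x$prior_sd))
  cat(sprintf("  sensory noise: sigma_R(N) = %g * N^%g\n",
              x$noise_k, x$noise_exponent))
  cat(sprintf("  motor jitter SD: %g\n", x$response_jitter_sd))
  invisible(x)
}

#' Default per-condition observers
#'
#' One observer per cue-validity condition, sharing the prior (centred at 15
#' dots, SD 5) and square-root noise scaling, and differing only in the noise
#' coefficient `noise_k`, ordered VSL < IS < ID: diverting attention away
#' from the cued object raises sensory noise, which the central prior then
#' converts into stronger compression. The coefficients correspond to
#' coefficients of variation of roughly 0.15, 0.19 and 0.26 at mid-range
#' numerosities.
#'
#' @param prior_mean,prior_sd Shared prior parameters.
#' @param noise_k Named numeric vector of noise coefficients for the VSL, IS
#'   and ID conditions.
#' @param noise_exponent Shared sensory-noise exponent.
#' @param response_jitter_sd Shared motor-noise SD.
#'
#' @return Named list of [bayes_observer()] objects (`VSL`, `IS`, `ID`).
#' @export
default_observers <- function(prior_mean = 15, prior_sd = 5,
                              noise_k = c(VSL = 0.58, IS = 0.74, ID = 1.0),
                              noise_exponent = 0.5,
                              response_jitter_sd = 0.5) {
  if (!all(conditions() %in% names(noise_k))) {
    stop("`noise_k` must be named with VSL, IS and ID entries.")
  }
  lapply(stats::setNames(conditions(), conditions()), function(cc) {
    bayes_observer(prior_mean = prior_mean, prior_sd = prior_sd,
                   noise_k = noise_k[[cc]], noise_exponent = noise_exponent,
                   response_jitter_sd = response_jitter_sd)
  })
}

#' Reaction-time distribution parameters for one condition
#'
#' Simulated reaction times follow a shifted log-normal: a fixed non-decision
#' shift plus a log-normal component whose moments are chosen so the overall
#' distribution has the requested mean and SD. With `sd_rt = 0` the
#' distribution degenerates to a point mass at `mean_rt`.
#'
#' @param mean_rt Mean reaction time in seconds; must exceed `shift`.
#' @param sd_rt Standard deviation in seconds; must be non-negative.
#' @param shift Non-decision shift in seconds (strictly positive support
#'   floor).
#'
#' @return An object of class `rt_params`.
#' @export
rt_params <- function(mean_rt, sd_rt, shift = 0.25) {
  if (!is.finite(mean_rt) || !is.finite(sd_rt) || !is.finite(shift)) {
    stop("Reaction-time parameters must be finite.")
  }
  if (sd_rt < 0) stop("`sd_rt` must be non-negative.")
  if (shift < 0) stop("`shift` must be non-negative.")
  if (mean_rt <= shift) stop("`mean_rt` must exceed `shift`.")
  structure(list(mean_rt = mean_rt, sd_rt = sd_rt, shift = shift),
            class = "rt_params")
}

#' Default per-condition reaction-time model
#'
#' Means echo the ordering reported for cued enumeration: valid same-location
#' responses are fastest (1.07 s) and invalid different-object responses
#' slowest (1.27 s), with invalid same-object in between (1.13 s).
#'
#' @return Named list of [rt_params()] objects (`VSL`, `IS`, `ID`).
#' @export
default_rt_model <- function() {
  list(VSL = rt_params(1.07, 0.14),
       IS  = rt_params(1.13, 0.17),
       ID  = rt_params(1.27, 0.20))
}

#' Draw reaction times from a shifted log-normal
#'
#' @param n Number of draws.
#' @param params An [rt_params()] object.
#' @return Numeric vector of `n` strictly positive reaction times (seconds).
#' @export
#' @examples
#' set.seed(1)
#' mean(generate_rt(1000, rt_params(1.07, 0.14)))
generate_rt <- function(n, params) {
  stopifnot(inherits(params, "rt_params"))
  if (params$sd_rt == 0) return(rep(params$mean_rt, n))
  m <- params$mean_rt - params$shift
  sdlog <- sqrt(log(1 + (params$sd_rt / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  params$shift + stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

# Canonical condition labels, in cue-validity order.
conditions <- function() c("VSL", "IS", "ID")
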