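#' Simulate one session of the cued number-line task
#'
#' Generates a trial table with the statistical structure of a
#' cue-validity enumeration session. Per trial: the condition is drawn
#' i.i.d. with the design's probabilities, the numerosity uniformly from
#' the design's range, and the response is produced by the condition's
#' central-tendency observer — the posterior mean of [posterior_mean()]
#' plus Gaussian noise — clamped to the number line. Reaction times come
#' from the condition's shifted log-normal model, and half the trials are
#' flagged as area-equated stimulus controls.
#'
#' The response noise has two components: sensory scatter with SD
#' `sigma_R(N)` — the same likelihood width that sets the posterior-mean
#' shrinkage, so response variability inherits the noise power law — and
#' constant motor jitter with SD `response_jitter_sd`. With
#' `sensory_scatter = FALSE` only the motor jitter is applied, which (with
#' zero jitter) yields the deterministic mean-observer mapping — useful for
#' validating downstream fits against exact identities.
#'
#' @param design A [session_design()].
#' @param observers Named list of per-condition [bayes_observer()]s
#'   (`VSL`, `IS`, `ID`).
#' @param rt_model Named list of per-condition [rt_params()].
#' @param subject_id Subject identifier stored in the table.
#' @param session Session index stored in the table.
#' @param sensory_scatter Include sensory noise in the response (default
#'   `TRUE`)?
#' @param seed Optional RNG seed; identical inputs and seed reproduce the
#'   table exactly.
#' @return Data frame with columns `subject_id`, `session`, `trial_index`,
#'   `condition`, `numerosity`, `response`, `rt`, `area_control`,
#'   `is_training`.
#' @export
#' @examples
#' tr <- simulate_session(session_design(), seed = 1)
#' head(tr)
simulate_session <- function(design = session_design(),
                             observers = default_observers(),
                             rt_model = default_rt_model(),
                             subject_id = "s01",
                             session = 1L,
                             sensory_scatter = TRUE,
                             seed = NULL) {
  stopifnot(inherits(design, "session_design"))
  if (!all(conditions() %in% names(observers))) {
    stop("`observers` must have VSL, IS and ID entries.")
  }
  if (!all(conditions() %in% names(rt_model))) {
    stop("`rt_model` must have VSL, IS and ID entries.")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- design$trials_per_session
  cond <- sample(conditions(), n, replace = TRUE,
                 prob = c(design$p_vsl, design$p_is, design$p_id))
  nn <- sample(seq(design$n_min, design$n_max), n, replace = TRUE)
  area_control <- sample(c(TRUE, FALSE), n, replace = TRUE)

  response <- numeric(n)
  rt <- numeric(n)
  for (cc in conditions()) {
    idx <- which(cond == cc)
    if (!length(idx)) next
    obs <- observers[[cc]]
    sR <- sigma_r(nn[idx], obs$noise_k, obs$noise_exponent)
    mu <- posterior_mean(nn[idx], obs$prior_mean, obs$prior_sd, sR)
    noise_sd <- if (sensory_scatter) {
      sqrt(sR^2 + obs$response_jitter_sd^2)
    } else {
      rep(obs$response_jitter_sd, length(idx))
    }
    response[idx] <- pmin(pmax(mu + stats::rnorm(length(idx), 0, noise_sd),
                               design$line_min), design$line_max)
    rt[idx] <- generate_rt(length(idx), rt_model[[cc]])
  }

  data.frame(
    subject_id = subject_id,
    session = as.integer(session),
    trial_index = seq_len(n),
    condition = cond,
    numerosity = nn,
    response = response,
    rt = rt,
    area_control = area_control,
    is_training = seq_len(n) <= design$n_training,
    stringsAsFactors = FALSE
  )
}

#' Simulate a full multi-subject experiment
#'
#' Runs `n_subjects` simulated subjects through all sessions of the design.
#' Between-subject heterogeneity is introduced by scaling every condition's
#' sensory-noise coefficient `noise_k` by a common subject-level log-normal
#' factor (`exp(rnorm(1, 0, subject_sd))`): noisier subjects are noisier in
#' all conditions, preserving the VSL < IS < ID noise ordering within each
#' subject while spreading subjects along the internal-noise axis.
#'
#' @param n_subjects Number of simulated subjects (default 15).
#' @param design A [session_design()].
#' @param observers Named per-condition observer list (the template whose
#'   `noise_k` values are scaled per subject).
#' @param rt_model Named per-condition [rt_params()] list.
#' @param subject_sd SD of the subject-level log-normal noise factor;
#'   0 gives identical observers for everyone.
#' @param sensory_scatter Passed to [simulate_session()].
#' @param seed Optional master seed; the whole experiment is reproducible
#'   from it.
#' @return Trial data frame (all subjects and sessions row-bound), with
#'   subject ids `s01`, `s02`, ...
#' @export
simulate_experiment <- function(n_subjects = 15,
                                design = session_design(),
                                observers = default_observers(),
                                rt_model = default_rt_model(),
                                subject_sd = 0.25,
                                sensory_scatter = TRUE,
                                seed = NULL) {
  if (n_subjects < 1) stop("`n_subjects` must be positive.")
  if (subject_sd < 0) stop("`subject_sd` must be non-negative.")
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_subjects * design$n_sessions)
  k <- 1L
  for (s in seq_len(n_subjects)) {
    f <- exp(stats::rnorm(1, 0, subject_sd))
    obs_s <- lapply(observers, function(o) {
      bayes_observer(prior_mean = o$prior_mean, prior_sd = o$prior_sd,
                     noise_k = o$noise_k * f,
                     noise_exponent = o$noise_exponent,
                     response_jitter_sd = o$response_jitter_sd)
    })
    for (ss in seq_len(design$n_sessions)) {
      out[[k]] <- simulate_session(design, obs_s, rt_model,
                                   subject_id = sprintf("s%02d", s),
                                   session = ss,
                                   sensory_scatter = sensory_scatter,
                                   seed = NULL)
      k <- k + 1L
    }
  }
  do.call(rbind, out)
}
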