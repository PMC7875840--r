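#' Sensory-noise power law
#'
#' Standard deviation of the sensory (likelihood) distribution at numerosity
#' `n`: `sigma_R(n) = noise_k * n^noise_exponent`. An exponent of 0 gives
#' constant noise, 1 gives Weber-law proportional noise; number-line
#' estimation data are best described by intermediate, near-square-root
#' scaling.
#'
#' @param n Numerosity (vectorised), `n >= 1`.
#' @param noise_k Positive noise coefficient.
#' @param noise_exponent Exponent of the power law.
#' @return Numeric vector of positive standard deviations.
#' @export
#' @examples
#' sigma_r(16, noise_k = 0.15, noise_exponent = 0.5)  # 0.6
sigma_r <- function(n, noise_k, noise_exponent) {
  if (any(n < 1)) stop("`n` must be at least 1.")
  if (noise_k <= 0) stop("`noise_k` must be positive.")
  noise_k * n^noise_exponent
}

#' Posterior mean of the central-tendency observer
#'
#' The Gaussian likelihood centred on the stimulus `n` (SD `sigma_R`) is
#' multiplied point-wise with the Gaussian prior (mean `prior_mean`, SD
#' `prior_sd`); the product is again Gaussian and its mean — the model's
#' predicted response — is the precision-weighted average
#'
#' \deqn{\hat R = \frac{\bar P \sigma_R^2 + n\, \sigma_P^2}{\sigma_R^2 + \sigma_P^2}.}
#'
#' The prediction always lies between `n` and the prior mean: it equals `n`
#' when `sigma_R = 0` and approaches `prior_mean` as `sigma_R` grows. Because
#' `sigma_R` itself grows with numerosity, large numerosities are drawn
#' towards the prior more strongly than small ones, producing a compressive
#' number-line mapping.
#'
#' @param n Numerosity (vectorised).
#' @param prior_mean Prior mean, in dots.
#' @param prior_sd Prior SD; must be positive (a zero prior SD together with
#'   a zero `sigma_R` leaves the posterior undefined unless `n` equals the
#'   prior mean).
#' @param sigma_R Likelihood SD(s), non-negative; recycled against `n`.
#' @return Numeric vector of predicted responses.
#' @export
#' @examples
#' posterior_mean(5, prior_mean = 15, prior_sd = 5, sigma_R = 3)  # 260/34
posterior_mean <- function(n, prior_mean, prior_sd, sigma_R) {
  if (any(sigma_R < 0)) stop("`sigma_R` must be non-negative.")
  if (prior_sd < 0) stop("`prior_sd` must be non-negative.")
  if (prior_sd == 0) {
    if (any(sigma_R == 0 & n != prior_mean)) {
      stop("Posterior undefined: both prior_sd and sigma_R are zero with n != prior_mean.")
    }
    return(ifelse(sigma_R == 0, n, rep(prior_mean, length.out = length(n))))
  }
  w <- prior_sd^2 / (sigma_R^2 + prior_sd^2)
  w * n + (1 - w) * prior_mean
}

#' Weight given to the sensory evidence
#'
#' In the ideal-observer formulation the response is a convex blend
#' `W_L * x + (1 - W_L) * prior_mean` of the sensory magnitude `x` and the
#' central prior, with
#'
#' \deqn{W_L = \frac{\sigma_P^2}{x^2 WF^2 + \sigma_P^2},}
#'
#' where `WF` is a Weber-fraction-like coefficient so that the sensory SD is
#' `x * WF`. `W_L` lies in (0, 1], equals 1 for perfect evidence (`wf = 0`)
#' or a flat prior, and decreases with magnitude: noisier (larger) magnitudes
#' lean more on the prior. Identical to [posterior_mean()] with
#' `sigma_R = x * wf`.
#'
#' @param x Positive magnitude(s).
#' @param wf Non-negative Weber fraction.
#' @param prior_sd Positive prior SD.
#' @return Weights in (0, 1], same length as `x`.
#' @export
#' @examples
#' likelihood_weight(15, wf = 0.2, prior_sd = 5)  # 25/34
likelihood_weight <- function(x, wf, prior_sd) {
  if (any(x <= 0)) stop("`x` must be positive.")
  if (wf < 0) stop("`wf` must be non-negative.")
  if (prior_sd <= 0) stop("`prior_sd` must be positive.")
  prior_sd^2 / (x^2 * wf^2 + prior_sd^2)
}

#' Predicted number-line mapping of an observer
#'
#' Evaluates the posterior-mean response at each numerosity, with the
#' likelihood width given by the observer's noise power law. When observed
#' mean responses are supplied, the goodness of fit R-squared
#' (1 - RSS/TSS) is attached.
#'
#' @param observer A [bayes_observer()].
#' @param numerosities Numerosities at which to predict.
#' @param observed_means Optional vector of observed mean responses, matched
#'   to `numerosities`.
#' @return Object of class `mapping_prediction` with fields `numerosities`,
#'   `predicted_response`, `params` and (possibly `NA`) `r_squared`.
#' @export
predict_mapping <- function(observer, numerosities, observed_means = NULL) {
  stopifnot(inherits(observer, "bayes_observer"))
  if (length(numerosities) == 0) stop("`numerosities` must be non-empty.")
  sR <- sigma_r(numerosities, observer$noise_k, observer$noise_exponent)
  pred <- posterior_mean(numerosities, observer$prior_mean, observer$prior_sd, sR)
  r2 <- NA_real_
  if (!is.null(observed_means)) {
    if (length(observed_means) != length(numerosities)) {
      stop("`observed_means` must match `numerosities` in length.")
    }
    r2 <- r_squared(observed_means, pred)
  }
  structure(
    list(numerosities = numerosities, predicted_response = pred,
         params = observer, r_squared = r2),
    class = "mapping_prediction"
  )
}

#' @export
print.mapping_prediction <- function(x, ...) {
  cat("Central-tendency mapping prediction over N in [",
      min(x$numerosities), ", ", max(x$numerosities), "]\n", sep = "")
  cat(sprintf("  prior Normal(%g, %g), sigma_R(N) = %g * N^%g\n",
              x$params$prior_mean, x$params$prior_sd,
              x$params$noise_k, x$params$noise_exponent))
  if (!is.na(x$r_squared)) cat(sprintf("  R-squared vs data: %.3f\n", x$r_squared))
  invisible(x)
}

r_squared <- function(observed, predicted) {
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) return(NA_real_)
  1 - sum((observed - predicted)^2) / tss
}

#' Fit the width of the central prior to mean number-line responses
#'
#' Given mean responses per numerosity and a specification of the sensory
#' noise, searches over the prior SD (and optionally the prior mean) for the
#' central-tendency mapping that maximises variance explained,
#' R-squared = 1 - RSS/TSS. The search combines a coarse log-spaced
#' grid with [stats::optimize()] refinement inside the bracketing interval,
#' so a flat-prior (identity) dataset pegs the prior SD at the upper bound
#' rather than failing.
#'
#' @param mean_responses Data frame with columns `numerosity` and
#'   `mean_response`; at least 4 numerosities.
#' @param sigma_r_spec Sensory-noise specification: either a list
#'   `list(noise_k =, noise_exponent =)` for the power law of [sigma_r()], or
#'   a data frame with columns `numerosity` and `sigma_r` giving the
#'   likelihood SD at each tested numerosity.
#' @param prior_mean_mode How the prior mean is handled: `"fixed_value"`
#'   (use `prior_mean`, default 15), `"fixed_midpoint"` (midpoint of the
#'   tested numerosity range), or `"free"` (estimated together with the SD).
#' @param prior_mean Prior mean used by `"fixed_value"`, or the starting
#'   value for `"free"`.
#' @param prior_sd_bounds Search interval for the prior SD.
#' @return Object of class `prior_fit`: fitted `prior_mean`, `prior_sd`,
#'   `r_squared`, the predicted mapping, and (when the noise spec is
#'   parametric) a fitted [bayes_observer()].
#' @export
fit_prior <- function(mean_responses, sigma_r_spec,
                      prior_mean_mode = c("fixed_value", "fixed_midpoint", "free"),
                      prior_mean = 15,
                      prior_sd_bounds = c(0.1, 1000)) {
  prior_mean_mode <- match.arg(prior_mean_mode)
  if (!all(c("numerosity", "mean_response") %in% names(mean_responses))) {
    stop("`mean_responses` needs columns `numerosity` and `mean_response`.")
  }
  mean_responses <- mean_responses[order(mean_responses$numerosity), ]
  nn <- mean_responses$numerosity
  obs <- mean_responses$mean_response
  if (length(nn) < 4) stop("Need mean responses for at least 4 numerosities.")
  if (stats::var(obs) == 0) stop("Degenerate data: all mean responses are equal.")

  parametric <- is.list(sigma_r_spec) && !is.data.frame(sigma_r_spec) &&
    all(c("noise_k", "noise_exponent") %in% names(sigma_r_spec))
  if (parametric) {
    sR <- sigma_r(nn, sigma_r_spec$noise_k, sigma_r_spec$noise_exponent)
  } else if (is.data.frame(sigma_r_spec)) {
    if (!all(c("numerosity", "sigma_r") %in% names(sigma_r_spec))) {
      stop("Tabular `sigma_r_spec` needs columns `numerosity` and `sigma_r`.")
    }
    idx <- match(nn, sigma_r_spec$numerosity)
    if (anyNA(idx)) stop("`sigma_r_spec` is missing some tested numerosities.")
    sR <- sigma_r_spec$sigma_r[idx]
  } else {
    stop("Unrecognised `sigma_r_spec`.")
  }

  r2_at <- function(psd, pm) {
    r_squared(obs, posterior_mean(nn, pm, psd, sR))
  }

  fit_sd_given_mean <- function(pm) {
    grid <- exp(seq(log(prior_sd_bounds[1]), log(prior_sd_bounds[2]),
                    length.out = 200))
    vals <- vapply(grid, r2_at, numeric(1), pm = pm)
    i <- which.max(vals)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(function(s) -r2_at(s, pm), interval = c(lo, hi),
                           tol = 1e-7)
    best <- if (-opt$objective >= vals[i]) {
      c(opt$minimum, -opt$objective)
    } else {
      c(grid[i], vals[i])
    }
    list(prior_sd = best[1], r_squared = best[2])
  }

  if (prior_mean_mode == "free") {
    obj <- function(p) -r2_at(exp(p[2]), p[1])
    opt <- stats::optim(c(prior_mean, log(mean(prior_sd_bounds))), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    pm_hat <- opt$par[1]
    refined <- fit_sd_given_mean(pm_hat)
    psd_hat <- refined$prior_sd; r2 <- refined$r_squared
  } else {
    pm_hat <- if (prior_mean_mode == "fixed_midpoint") {
      (min(nn) + max(nn)) / 2
    } else {
      prior_mean
    }
    res <- fit_sd_given_mean(pm_hat)
    psd_hat <- res$prior_sd; r2 <- res$r_squared
  }

  observer <- if (parametric) {
    bayes_observer(prior_mean = pm_hat, prior_sd = psd_hat,
                   noise_k = sigma_r_spec$noise_k,
                   noise_exponent = sigma_r_spec$noise_exponent,
                   response_jitter_sd = 0)
  } else NULL

  structure(
    list(prior_mean = pm_hat, prior_sd = psd_hat, r_squared = r2,
         prior_mean_mode = prior_mean_mode,
         sigma_r = data.frame(numerosity = nn, sigma_r = sR),
         predicted = data.frame(numerosity = nn,
                                mean_response = obs,
                                predicted = posterior_mean(nn, pm_hat, psd_hat, sR)),
         observer = observer),
    class = "prior_fit"
  )
}

#' @export
print.prior_fit <- function(x, ...) {
  cat("Central-tendency prior fit\n")
  cat(sprintf("  prior mean %.3f (%s), prior SD %.3f\n",
              x$prior_mean, x$prior_mean_mode, x$prior_sd))
  cat(sprintf("  R-squared = %.4f over %d numerosities\n",
              x$r_squared, nrow(x$predicted)))
  invisible(x)
}

#' Predicted non-linearity as a function of internal noise
#'
#' Simulates an ideal observer whose sensory SD is proportional to magnitude
#' (`sigma_R = N * WF`) for each Weber fraction in `wf_grid`: responses are
#' the posterior mean plus Gaussian sensory scatter, clamped to the number
#' line. For each noise level the function records the internal noise
#' (SD of response/numerosity ratios) and the exponent of the best-fitting
#' power function — tracing out the model's prediction that noisier
#' observers show stronger compressive non-linearity.
#'
#' @param prior_sd Prior SD of the simulated observer (default 17 dots,
#'   derived from the spread of the stimulus range).
#' @param wf_grid Positive Weber fractions to simulate.
#' @param numerosities Numerosities tested (each shown `n_sim` times).
#' @param n_sim Simulated trials per numerosity per noise level.
#' @param prior_mean Prior mean; defaults to the midpoint of `numerosities`.
#' @param line Number-line bounds used to clamp responses.
#' @param seed Optional RNG seed for reproducibility.
#' @return Data frame with columns `wf`, `internal_noise`, `exponent`,
#'   `scale`.
#' @export
nonlinearity_vs_noise_curve <- function(prior_sd = 17,
                                        wf_grid = seq(0.05, 0.5, by = 0.05),
                                        numerosities = 5:30,
                                        n_sim = 100,
                                        prior_mean = NULL,
                                        line = c(1, 35),
                                        seed = NULL) {
  if (any(wf_grid < 0)) stop("`wf_grid` must be non-negative.")
  if (n_sim < 100) stop("`n_sim` must be at least 100.")
  if (is.null(prior_mean)) prior_mean <- (min(numerosities) + max(numerosities)) / 2
  if (!is.null(seed)) set.seed(seed)
  nn <- rep(numerosities, each = n_sim)
  out <- lapply(wf_grid, function(wf) {
    sR <- nn * wf
    resp <- posterior_mean(nn, prior_mean, prior_sd, sR) +
      stats::rnorm(length(nn), 0, sR)
    resp <- pmin(pmax(resp, line[1]), line[2])
    fit <- fit_power_mle(nn, resp, n_starts = 3)
    data.frame(wf = wf,
               internal_noise = stats::sd(resp / nn),
               exponent = fit$exponent,
               scale = fit$scale)
  })
  do.call(rbind, out)
}
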