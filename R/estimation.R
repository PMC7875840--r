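#' Negative log-likelihood of the linear scalar-variability model
#'
#' Responses are modelled as Gaussian around a linear mapping of numerosity,
#' with a standard deviation that grows in proportion to the predicted
#' magnitude (scalar variability): `mu_k = intercept + slope * N_k`,
#' `sd_k = sigma_n * mu_k`. `sigma_n` is therefore the coefficient of
#' variation of the estimates. Returns
#' `-sum(log Normal(R_k; mu_k, sd_k))`.
#'
#' A non-positive predicted SD for any trial makes the likelihood undefined;
#' in that case a large finite penalty (increasing with the violation) is
#' returned so that numerical optimisers are pushed back into the valid
#' region. The penalised value carries attribute `penalized = TRUE`.
#'
#' @param intercept,slope Linear mapping parameters.
#' @param sigma_n Scalar-variability coefficient (> 0 for a valid model).
#' @param numerosity,response Equal-length trial vectors.
#' @return Scalar negative log-likelihood.
#' @export
#' @examples
#' negloglik_linear(0, 1, 0.1, 10, 10)  # 0.5 * log(2*pi), density at the mode
negloglik_linear <- function(intercept, slope, sigma_n, numerosity, response) {
  stopifnot(length(numerosity) == length(response), length(numerosity) >= 1)
  mu <- intercept + slope * numerosity
  s <- sigma_n * mu
  penalized_or_nll(mu, s, response)
}

#' Negative log-likelihood of the power-law scalar-variability model
#'
#' As [negloglik_linear()], but with a power-function mean
#' `mu_k = scale * N_k^exponent` and SD `sd_k = sigma_n * mu_k`. An exponent
#' below 1 corresponds to a compressive number-line mapping.
#'
#' @param scale,exponent Power-function parameters.
#' @param sigma_n Scalar-variability coefficient.
#' @param numerosity,response Equal-length trial vectors.
#' @return Scalar negative log-likelihood.
#' @export
negloglik_power <- function(scale, exponent, sigma_n, numerosity, response) {
  stopifnot(length(numerosity) == length(response), length(numerosity) >= 1)
  mu <- scale * numerosity^exponent
  s <- sigma_n * mu
  penalized_or_nll(mu, s, response)
}

penalized_or_nll <- function(mu, s, response) {
  if (any(!is.finite(mu)) || any(!is.finite(s)) || any(s <= 0)) {
    bad <- sum(pmax(0, -s), na.rm = TRUE)
    out <- 1e10 + 1e6 * (bad + sum(!is.finite(s)))
    attr(out, "penalized") <- TRUE
    return(out)
  }
  -sum(stats::dnorm(response, mean = mu, sd = s, log = TRUE))
}

default_linear_bounds <- function() {
  list(intercept = c(-10, 20), slope = c(1e-6, 5), sigma_n = c(1e-4, 2))
}

default_power_bounds <- function() {
  list(scale = c(1e-6, 5), exponent = c(1e-6, 2), sigma_n = c(1e-4, 2))
}

clip <- function(x, b) pmin(pmax(x, b[1]), b[2])

# Shared multi-start bounded optimisation driver. `starts` is a matrix with
# one start per row; returns the best converged optim() result (or the best
# overall with converged = FALSE if no start converged). L-BFGS-B can abort
# its line search on numerically flat optima (convergence code 52); such
# endpoints are polished with a bounded (clipped) Nelder-Mead pass and
# accepted if that converges.
multistart_optim <- function(starts, nll, lower, upper) {
  nll_boxed <- function(p) {
    pc <- pmin(pmax(p, lower), upper)
    nll(pc) + 1e4 * sum((p - pc)^2)
  }
  best <- NULL
  best_ok <- FALSE
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], nll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    if (res$convergence != 0) {
      nm <- tryCatch(
        stats::optim(res$par, nll_boxed, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-10)),
        error = function(e) NULL
      )
      if (!is.null(nm) && is.finite(nm$value) && nm$value <= res$value + 1e-8) {
        nm$par <- pmin(pmax(nm$par, lower), upper)
        nm$value <- nll(nm$par)
        res <- nm
      }
    }
    ok <- res$convergence == 0
    if (is.null(best) ||
        (ok && !best_ok) ||
        (ok == best_ok && res$value < best$value)) {
      best <- res
      best_ok <- ok
    }
  }
  list(result = best, converged = best_ok)
}

random_starts <- function(n, bounds, data_start) {
  lows <- vapply(bounds, `[`, numeric(1), 1)
  ups <- vapply(bounds, `[`, numeric(1), 2)
  rand <- if (n > 1) {
    t(replicate(n - 1, stats::runif(length(bounds), lows, ups)))
  } else NULL
  rbind(matrix(data_start, nrow = 1), rand)
}

#' Maximum-likelihood fit of the linear scalar-variability model
#'
#' Jointly estimates intercept, slope and the scalar-variability coefficient
#' `sigma_n` by minimising [negloglik_linear()] with bounded quasi-Newton
#' (L-BFGS-B) from multiple starting points: one data-driven start from an
#' ordinary least-squares fit, plus `n_starts - 1` random starts drawn
#' uniformly within the bounds. Combining likelihood across all target
#' values makes the estimate robust to unbalanced designs where some
#' conditions contribute few trials.
#'
#' @param numerosity,response Trial vectors; at least 10 trials spanning at
#'   least 3 distinct numerosities.
#' @param init Optional numeric start `c(intercept, slope, sigma_n)`
#'   replacing the data-driven start.
#' @param bounds Named list of length-2 ranges for `intercept`, `slope` and
#'   `sigma_n` (defaults: [-10, 20], (0, 5], (1e-4, 2]).
#' @param n_starts Total number of optimisation starts.
#' @return Object of class `ml_fit` with fields `model = "linear"`,
#'   `intercept`, `slope`, `sigma_n`, `log_lik`, `n_trials`, `converged`.
#'   If no start converges the parameters are `NA` and `converged` is
#'   `FALSE` (with a warning) — never silently defaulted.
#' @export
fit_linear_mle <- function(numerosity, response, init = NULL, bounds = NULL,
                           n_starts = 10) {
  check_fit_input(numerosity, response)
  bounds <- bounds %||% default_linear_bounds()
  if (is.null(init)) {
    ls <- stats::lm.fit(cbind(1, numerosity), response)
    a0 <- clip(ls$coefficients[1], bounds$intercept)
    b0 <- clip(ls$coefficients[2], bounds$slope)
    mu0 <- pmax(a0 + b0 * numerosity, 0.1)
    s0 <- clip(stats::sd(ls$residuals) / mean(mu0), bounds$sigma_n)
    init <- c(a0, b0, s0)
  }
  starts <- random_starts(n_starts, bounds, init)
  nll <- function(p) {
    as.numeric(negloglik_linear(p[1], p[2], p[3], numerosity, response))
  }
  ms <- multistart_optim(starts, nll,
                         lower = c(bounds$intercept[1], bounds$slope[1], bounds$sigma_n[1]),
                         upper = c(bounds$intercept[2], bounds$slope[2], bounds$sigma_n[2]))
  as_ml_fit(ms, model = "linear",
            par_names = c("intercept", "slope", "sigma_n"),
            n_trials = length(numerosity))
}

#' Maximum-likelihood fit of the power-function model
#'
#' Estimates the scaling factor, exponent and scalar-variability coefficient
#' of the power mapping `mu = scale * N^exponent`, `sd = sigma_n * mu`, by
#' the same multi-start bounded optimisation as [fit_linear_mle()]. The
#' data-driven start comes from a log-log least-squares regression. A fitted
#' exponent below 1 indicates a compressive number-line mapping
#' (overestimation of small, underestimation of large numerosities).
#'
#' @inheritParams fit_linear_mle
#' @param init Optional numeric start `c(scale, exponent, sigma_n)`.
#' @param bounds Named list of ranges for `scale`, `exponent`, `sigma_n`
#'   (defaults: (0, 5], (0, 2], (1e-4, 2]).
#' @return Object of class `ml_fit` with fields `model = "power"`, `scale`,
#'   `exponent`, `sigma_n`, `log_lik`, `n_trials`, `converged`. A warning is
#'   raised if the fitted exponent falls outside (0, 1.5], the plausible
#'   range for this task.
#' @export
fit_power_mle <- function(numerosity, response, init = NULL, bounds = NULL,
                          n_starts = 10) {
  check_fit_input(numerosity, response)
  bounds <- bounds %||% default_power_bounds()
  if (is.null(init)) {
    rpos <- pmax(response, 0.1)
    ll <- stats::lm.fit(cbind(1, log(numerosity)), log(rpos))
    s0 <- clip(exp(ll$coefficients[1]), bounds$scale)
    e0 <- clip(ll$coefficients[2], bounds$exponent)
    mu0 <- s0 * numerosity^e0
    sg0 <- clip(stats::sd(response - mu0) / mean(mu0), bounds$sigma_n)
    init <- c(s0, e0, sg0)
  }
  starts <- random_starts(n_starts, bounds, init)
  nll <- function(p) {
    as.numeric(negloglik_power(p[1], p[2], p[3], numerosity, response))
  }
  ms <- multistart_optim(starts, nll,
                         lower = c(bounds$scale[1], bounds$exponent[1], bounds$sigma_n[1]),
                         upper = c(bounds$scale[2], bounds$exponent[2], bounds$sigma_n[2]))
  fit <- as_ml_fit(ms, model = "power",
                   par_names = c("scale", "exponent", "sigma_n"),
                   n_trials = length(numerosity))
  if (isTRUE(fit$converged) && (fit$exponent <= 0 || fit$exponent > 1.5)) {
    warning("Fitted exponent ", format(fit$exponent, digits = 3),
            " lies outside the typical (0, 1.5] range for this task.")
  }
  fit
}

check_fit_input <- function(numerosity, response) {
  if (length(numerosity) != length(response)) {
    stop("`numerosity` and `response` must have equal length.")
  }
  if (length(numerosity) < 10) stop("Need at least 10 trials to fit.")
  if (length(unique(numerosity)) < 3) {
    stop("Need at least 3 distinct numerosities to fit.")
  }
}

as_ml_fit <- function(ms, model, par_names, n_trials) {
  if (is.null(ms$result)) {
    warning("Optimiser failed for every start; returning an unconverged fit.")
    pars <- stats::setNames(rep(NA_real_, 3), par_names)
    return(structure(c(list(model = model), as.list(pars),
                       list(log_lik = NA_real_, n_trials = n_trials,
                            converged = FALSE)),
                     class = "ml_fit"))
  }
  if (!ms$converged) {
    warning("No optimisation start converged; best unconverged fit returned.")
  }
  pars <- stats::setNames(as.list(ms$result$par), par_names)
  structure(c(list(model = model), pars,
              list(log_lik = -ms$result$value, n_trials = n_trials,
                   converged = ms$converged)),
            class = "ml_fit")
}

#' @export
print.ml_fit <- function(x, ...) {
  cat(sprintf("Scalar-variability %s fit (%d trials)%s\n", x$model,
              x$n_trials, if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  if (x$model == "linear") {
    cat(sprintf("  intercept %.4f  slope %.4f  sigma_n %.4f\n",
                x$intercept, x$slope, x$sigma_n))
  } else {
    cat(sprintf("  scale %.4f  exponent %.4f  sigma_n %.4f\n",
                x$scale, x$exponent, x$sigma_n))
  }
  cat(sprintf("  log-likelihood %.3f\n", x$log_lik))
  invisible(x)
}

#' Power-law fit to response SD as a function of numerosity
#'
#' Fits `SD(N) = scale * N^exponent` by least squares in log-log space.
#' Summary SDs (one per numerosity) rather than raw trials are fitted, so a
#' simple regression is the appropriate tool: an exponent near 1 indicates
#' Weber-law scaling, near 0.5 square-root scaling, and 0 constant precision.
#'
#' @param sd_by_numerosity Data frame with columns `numerosity` and `sd`.
#'   Zero or negative SDs are dropped with a warning; at least 3 usable
#'   numerosities are required.
#' @return List with `scale`, `exponent`, `n_points` and `r_squared` (of the
#'   log-log regression).
#' @export
#' @examples
#' d <- data.frame(numerosity = 5:30, sd = 0.5 * sqrt(5:30))
#' fit_sd_power(d)  # scale 0.5, exponent 0.5
fit_sd_power <- function(sd_by_numerosity) {
  if (!all(c("numerosity", "sd") %in% names(sd_by_numerosity))) {
    stop("`sd_by_numerosity` needs columns `numerosity` and `sd`.")
  }
  d <- sd_by_numerosity[is.finite(sd_by_numerosity$sd), ]
  if (any(d$sd <= 0)) {
    warning(sum(d$sd <= 0), " numerosities with non-positive SD excluded.")
    d <- d[d$sd > 0, ]
  }
  if (nrow(d) < 3) stop("Need at least 3 numerosities with positive SD.")
  fit <- stats::lm(log(sd) ~ log(numerosity), data = d)
  ly <- log(d$sd)
  tss <- sum((ly - mean(ly))^2)
  list(scale = unname(exp(stats::coef(fit)[1])),
       exponent = unname(stats::coef(fit)[2]),
       n_points = nrow(d),
       r_squared = if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_)
}

#' Per-condition noise summaries of a trial table
#'
#' For each cue-validity condition computes: the internal noise — the SD of
#' response/numerosity ratios, the abscissa of the non-linearity-vs-noise
#' relationship; the coefficient of variation — the mean over numerosities
#' of SD(R | N)/N; and a table of response SDs per numerosity (defined only
#' for numerosities with at least 2 responses).
#'
#' @param trials Trial data frame with columns `condition`, `numerosity`,
#'   `response`.
#' @param min_n Minimum trials for a condition to be summarised (default 2);
#'   smaller conditions are omitted with a warning.
#' @return Object of class `noise_summary`: `$summary` (one row per
#'   condition: `condition`, `n_trials`, `internal_noise`, `cv`) and
#'   `$sd_by_numerosity` (`condition`, `numerosity`, `n`, `sd`).
#' @export
compute_noise_summary <- function(trials, min_n = 2) {
  stopifnot(all(c("condition", "numerosity", "response") %in% names(trials)))
  conds <- intersect(conditions(), unique(trials$condition))
  rows <- list(); sd_tabs <- list()
  for (cc in conds) {
    sub <- trials[trials$condition == cc, ]
    if (nrow(sub) < min_n) {
      warning("Condition ", cc, " has fewer than ", min_n,
              " trials and was omitted.")
      next
    }
    internal <- stats::sd(sub$response / sub$numerosity)
    agg <- stats::aggregate(response ~ numerosity, data = sub,
                            FUN = function(r) c(n = length(r), sd = stats::sd(r)))
    tab <- data.frame(condition = cc,
                      numerosity = agg$numerosity,
                      n = agg$response[, "n"],
                      sd = agg$response[, "sd"])
    tab <- tab[tab$n >= 2, ]
    cv <- mean(tab$sd / tab$numerosity)
    rows[[cc]] <- data.frame(condition = cc, n_trials = nrow(sub),
                             internal_noise = internal, cv = cv)
    sd_tabs[[cc]] <- tab
  }
  structure(
    list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         sd_by_numerosity = do.call(rbind, c(sd_tabs, list(make.row.names = FALSE)))),
    class = "noise_summary"
  )
}

#' @export
print.noise_summary <- function(x, ...) {
  cat("Per-condition noise summary\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
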