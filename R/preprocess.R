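#' Drop leading training trials from each session
#'
#' Removes the first `n_training` trials of every (subject, session) group,
#' by rank of `trial_index` within the group (so both 0- and 1-based trial
#' indices are handled). Order is otherwise preserved. Sessions with no more
#' than `n_training` trials lose all their trials, with a warning.
#'
#' @param trials Trial data frame with `subject_id`, `session`,
#'   `trial_index`.
#' @param n_training Number of leading trials to drop per session.
#' @return The trial data frame without training trials.
#' @export
drop_training <- function(trials, n_training = 20) {
  stopifnot(all(c("subject_id", "session", "trial_index") %in% names(trials)))
  if (n_training < 0) stop("`n_training` must be non-negative.")
  if (n_training == 0 || nrow(trials) == 0) return(trials)
  key <- interaction(trials$subject_id, trials$session, drop = TRUE)
  rank_in_session <- stats::ave(trials$trial_index, key,
                                FUN = function(x) rank(x, ties.method = "first"))
  sizes <- table(key)
  if (any(sizes <= n_training)) {
    warning(sum(sizes <= n_training), " session(s) with <= ", n_training,
            " trials lost all their trials to the training exclusion.")
  }
  trials[rank_in_session > n_training, , drop = FALSE]
}

#' Remove outlying responses by the 2-SD rule
#'
#' Within each group (by default subject x condition) the group mean and
#' sample SD of the responses are computed once, and responses lying strictly
#' more than `k_sd` standard deviations from the mean are removed. The rule
#' is single-pass: statistics are not recomputed after removal. Responses at
#' exactly `k_sd` SDs are kept ("more than" is strict), and zero-variance
#' groups lose nothing. Groups with fewer than 2 trials are passed through
#' untouched with a warning.
#'
#' @param trials Trial data frame with `response` and the grouping columns.
#' @param k_sd Cut-off in standard deviations (default 2).
#' @param group_by Character vector of grouping columns (default
#'   `c("subject_id", "condition")`; use `"condition"` alone to pool
#'   subjects).
#' @return List with `trials` (survivors, original order and content
#'   untouched) and `report`: a data frame with per-condition counts and
#'   fractions removed.
#' @export
#' @examples
#' d <- data.frame(subject_id = "s01", condition = "VSL",
#'                 response = c(rep(10, 9), 100))
#' remove_outliers(d)$report
remove_outliers <- function(trials, k_sd = 2,
                            group_by = c("subject_id", "condition")) {
  stopifnot("response" %in% names(trials))
  if (k_sd <= 0) stop("`k_sd` must be positive.")
  if (nrow(trials) == 0) {
    return(list(trials = trials,
                report = data.frame(condition = character(0),
                                    n_removed = integer(0),
                                    n_group = integer(0),
                                    fraction = numeric(0))))
  }
  missing_cols <- setdiff(group_by, names(trials))
  if (length(missing_cols)) {
    stop("Grouping column(s) not found: ", paste(missing_cols, collapse = ", "))
  }
  key <- interaction(trials[group_by], drop = TRUE)
  keep <- rep(TRUE, nrow(trials))
  small <- 0L
  for (g in levels(key)) {
    idx <- which(key == g)
    if (length(idx) < 2) {
      small <- small + 1L
      next
    }
    r <- trials$response[idx]
    m <- mean(r); s <- stats::sd(r)
    keep[idx] <- abs(r - m) <= k_sd * s
  }
  if (small > 0) {
    warning(small, " group(s) with fewer than 2 trials passed through untouched.")
  }
  cond <- if ("condition" %in% names(trials)) trials$condition else rep("all", nrow(trials))
  conds <- intersect(c(conditions(), "all"), unique(cond))
  report <- do.call(rbind, lapply(conds, function(cc) {
    in_c <- cond == cc
    data.frame(condition = cc,
               n_removed = sum(!keep & in_c),
               n_group = sum(in_c),
               fraction = if (sum(in_c)) sum(!keep & in_c) / sum(in_c) else NA_real_)
  }))
  list(trials = trials[keep, , drop = FALSE], report = report)
}

#' Exclude implausibly fast reaction times
#'
#' Drops trials with a reaction time strictly below `min_rt` (default 150
#' ms; trials at exactly the floor are kept). This filter belongs to the
#' reaction-time analysis branch only — response fits are not subject to it.
#'
#' @param trials Trial data frame with an `rt` column (seconds).
#' @param min_rt Floor in seconds; must be non-negative.
#' @return Filtered trials, with attributes `n_removed` and
#'   `fraction_removed`.
#' @export
filter_rt <- function(trials, min_rt = 0.150) {
  stopifnot("rt" %in% names(trials))
  if (min_rt < 0) stop("`min_rt` must be non-negative.")
  keep <- trials$rt >= min_rt
  out <- trials[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "fraction_removed") <- if (nrow(trials)) sum(!keep) / nrow(trials) else 0
  out
}

#' Apply the standard preprocessing to a trial table
#'
#' Runs the response-analysis exclusions in order: leading training trials
#' of each session are dropped ([drop_training()]), then responses more than
#' `k_sd` SDs from their group mean are removed ([remove_outliers()]).
#' The reaction-time floor is *not* applied here — it belongs to the RT
#' branch ([filter_rt()]) and its count enters the report separately.
#'
#' @param trials Raw trial data frame.
#' @param n_training Training trials per session.
#' @param k_sd Outlier cut-off in SDs.
#' @param group_by Grouping for the outlier rule.
#' @return List with `trials` (clean table) and `report`, a
#'   `cleaning_report`: `n_input`, `n_training_dropped`, per-condition
#'   outlier counts/fractions, `n_rt_dropped` (NA here), `n_output`.
#' @export
clean_trials <- function(trials, n_training = 20, k_sd = 2,
                         group_by = c("subject_id", "condition")) {
  n_input <- nrow(trials)
  t1 <- drop_training(trials, n_training)
  n_training_dropped <- n_input - nrow(t1)
  out <- remove_outliers(t1, k_sd = k_sd, group_by = group_by)
  n_outliers <- nrow(t1) - nrow(out$trials)
  report <- structure(
    list(n_input = n_input,
         n_training_dropped = n_training_dropped,
         outliers = out$report,
         n_outliers_dropped = n_outliers,
         n_rt_dropped = NA_integer_,
         n_output = nrow(out$trials)),
    class = "cleaning_report"
  )
  stopifnot(report$n_output ==
              report$n_input - report$n_training_dropped - report$n_outliers_dropped)
  list(trials = out$trials, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Preprocessing report\n")
  cat(sprintf("  input trials:      %d\n", x$n_input))
  cat(sprintf("  training dropped:  %d\n", x$n_training_dropped))
  cat(sprintf("  outliers dropped:  %d\n", x$n_outliers_dropped))
  for (i in seq_len(nrow(x$outliers))) {
    cat(sprintf("    %-3s %4d / %5d (%.2f%%)\n",
                x$outliers$condition[i], x$outliers$n_removed[i],
                x$outliers$n_group[i], 100 * x$outliers$fraction[i]))
  }
  if (!is.na(x$n_rt_dropped)) {
    cat(sprintf("  fast RTs dropped:  %d (RT branch only)\n", x$n_rt_dropped))
  }
  cat(sprintf("  output trials:     %d\n", x$n_output))
  invisible(x)
}
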