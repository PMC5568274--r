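#' Simulation configuration
#'
#' Bundle and validate every tunable parameter of the discrete-time
#' data-generating process. Defaults reproduce the study conditions: a
#' 10-interval (10-year) horizon, a 5\% intended drug-user rate, a constant
#' dose of 0.5 per interval, baseline per-interval event odds of 0.015
#' (\code{beta0 = log(0.015)}) and a null drug effect
#' (\code{beta1 = beta2 = beta3 = 0}).
#'
#' The per-interval event probability is logit-linear in three dose-group
#' indicators (low / moderate / high cumulative dose), see
#' \code{\link{event_probability}}. Cumulative dose is
#' \code{dose_per_interval} times the number of exposed intervals and is
#' cut into the three groups at \code{dose_cutpoints} (half-open on the
#' right: a dose exactly at a cutpoint belongs to the lower group).
#'
#' @param n_subjects total cohort size N.
#' @param intended_user_rate proportion of subjects assigned an intended
#'   drug-initiation time, in (0, 1). The realized user fraction is lower
#'   because subjects whose event precedes initiation are realized
#'   non-users.
#' @param n_intervals number of discrete time intervals (years).
#' @param dose_per_interval dose accrued during each exposed interval.
#' @param beta0 log-odds intercept of the per-interval event probability.
#' @param beta1,beta2,beta3 log-odds effects of the low, moderate and high
#'   cumulative-dose groups (0 under the null).
#' @param dose_cutpoints two strictly increasing positive cutpoints
#'   separating low/moderate and moderate/high cumulative dose.
#' @param seed integer seed; \code{\link{simulate_cohort}} is deterministic
#'   given the configuration.
#' @return an object of class \code{gtb_config} (a validated named list).
#' @examples
#' cfg <- sim_config(n_subjects = 1000, seed = 7)
#' cfg$beta0
#' @export
sim_config <- function(n_subjects = 5000,
                       intended_user_rate = 0.05,
                       n_intervals = 10,
                       dose_per_interval = 0.5,
                       beta0 = log(0.015),
                       beta1 = 0, beta2 = 0, beta3 = 0,
                       dose_cutpoints = c(1.5, 3.0),
                       seed = 1L) {
  cfg <- list(n_subjects = n_subjects,
              intended_user_rate = intended_user_rate,
              n_intervals = n_intervals,
              dose_per_interval = dose_per_interval,
              beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
              dose_cutpoints = dose_cutpoints,
              seed = seed)
  validate_config(cfg)
  cfg$n_subjects <- as.integer(n_subjects)
  cfg$n_intervals <- as.integer(n_intervals)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "gtb_config"
  cfg
}

config_error <- function(field, msg) {
  stop(structure(class = c("gtb_config_error", "error", "condition"),
                 list(message = sprintf("configuration error in '%s': %s", field, msg),
                      call = sys.call(-1))))
}

validate_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$n_subjects) || cfg$n_subjects < 1 || cfg$n_subjects != round(cfg$n_subjects))
    config_error("n_subjects", "must be a positive integer")
  if (!num1(cfg$intended_user_rate) || cfg$intended_user_rate <= 0 || cfg$intended_user_rate >= 1)
    config_error("intended_user_rate", "must lie strictly in (0, 1)")
  if (!num1(cfg$n_intervals) || cfg$n_intervals < 1 || cfg$n_intervals != round(cfg$n_intervals))
    config_error("n_intervals", "must be a positive integer")
  if (!num1(cfg$dose_per_interval) || cfg$dose_per_interval <= 0)
    config_error("dose_per_interval", "must be a positive real")
  for (b in c("beta0", "beta1", "beta2", "beta3"))
    if (!num1(cfg[[b]])) config_error(b, "must be a finite real")
  cp <- cfg$dose_cutpoints
  if (!is.numeric(cp) || length(cp) != 2L || any(!is.finite(cp)))
    config_error("dose_cutpoints", "must be two finite reals")
  if (!(cp[1] > 0 && cp[1] < cp[2]))
    config_error("dose_cutpoints", "must be strictly increasing and positive")
  if (cp[2] >= cfg$n_intervals * cfg$dose_per_interval)
    config_error("dose_cutpoints", "upper cutpoint must be below the maximum attainable dose")
  if (!num1(cfg$seed) || cfg$seed != round(cfg$seed))
    config_error("seed", "must be an integer")
  invisible(cfg)
}

#' @export
print.gtb_config <- function(x, ...) {
  cat("Discrete-time cohort simulation configuration\n")
  cat(sprintf("  N = %d subjects, %d intervals, intended user rate %.3f\n",
              x$n_subjects, x$n_intervals, x$intended_user_rate))
  cat(sprintf("  dose %.3g per interval, cutpoints (%.3g, %.3g)\n",
              x$dose_per_interval, x$dose_cutpoints[1], x$dose_cutpoints[2]))
  cat(sprintf("  beta0 = %.4f (p0 = %.5f), beta1..3 = %.4f, %.4f, %.4f\n",
              x$beta0, stats::plogis(x$beta0), x$beta1, x$beta2, x$beta3))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}
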