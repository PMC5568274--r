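#' Per-interval event probability
#'
#' The discrete-time hazard: probability of the event in one interval given
#' the current dose-group indicators, logit-linear in the three indicators.
#' At most one of \code{z1, z2, z3} may be 1 (the groups are exclusive).
#'
#' @param z1,z2,z3 binary indicators for the low, moderate and high
#'   cumulative-dose groups (all zero for a non-user interval).
#' @param beta0 log-odds intercept.
#' @param beta1,beta2,beta3 log-odds effects for the three groups.
#' @return probability strictly inside (0, 1); vectorized over indicators.
#' @examples
#' event_probability(0, 0, 0, beta0 = log(0.015))  # 0.015 / 1.015
#' @export
event_probability <- function(z1, z2, z3, beta0, beta1 = 0, beta2 = 0, beta3 = 0) {
  if (any(z1 + z2 + z3 > 1))
    stop("at most one of z1, z2, z3 may be 1")
  stats::plogis(beta0 + beta1 * z1 + beta2 * z2 + beta3 * z3)
}

#' Draw drug-initiation intervals
#'
#' Discrete-uniform draws on \{1, ..., n_intervals\} for the intended drug
#' users, using R's global random number stream (seed it with
#' \code{set.seed}; \code{\link{simulate_cohort}} seeds it from the
#' configuration).
#'
#' @param n_users number of intended users (>= 0).
#' @param n_intervals number of intervals.
#' @return integer vector of length \code{n_users}.
#' @export
draw_initiation_intervals <- function(n_users, n_intervals) {
  if (length(n_users) != 1L || !is.finite(n_users) || n_users < 0 || n_users != round(n_users))
    stop("'n_users' must be a nonnegative integer")
  if (n_users == 0) return(integer(0))
  sample.int(n_intervals, n_users, replace = TRUE)
}

#' Cumulative dose at an interval
#'
#' Dose accrued through interval \code{t} for a subject initiating at
#' interval \code{W}: the subject is exposed during interval W itself, so
#' the cumulative dose is \code{dose_per_interval * (t - W + 1)} for
#' \code{t >= W} and 0 before initiation (or for never-users,
#' \code{initiation_interval = NA}).
#'
#' @param initiation_interval initiation interval W (NA for non-users).
#' @param t interval index (>= 1).
#' @param dose_per_interval dose per exposed interval.
#' @return nonnegative cumulative dose; vectorized.
#' @export
cumulative_dose <- function(initiation_interval, t, dose_per_interval) {
  if (any(t < 1)) stop("'t' must be >= 1")
  exposed <- pmax(t - initiation_interval + 1, 0)
  exposed[is.na(initiation_interval)] <- 0
  dose_per_interval * exposed
}

#' Cumulative-dose category
#'
#' Cut a cumulative dose into \code{none} (zero dose), \code{low},
#' \code{moderate} or \code{high}. Boundaries are half-open: a dose exactly
#' equal to a cutpoint belongs to the lower group
#' (low: (0, c1], moderate: (c1, c2], high: (c2, Inf)).
#'
#' @param cumdose nonnegative cumulative dose (vectorized).
#' @param cutpoints two strictly increasing positive cutpoints.
#' @return factor with levels \code{none, low, moderate, high}.
#' @examples
#' dose_category(c(0, 1.5, 2, 5), cutpoints = c(1.5, 3))
#' @export
dose_category <- function(cumdose, cutpoints = c(1.5, 3.0)) {
  if (any(cumdose < 0)) stop("'cumdose' must be nonnegative")
  if (length(cutpoints) != 2L || !(cutpoints[1] > 0 && cutpoints[1] < cutpoints[2]))
    stop("'cutpoints' must be two increasing positive reals")
  codes <- dose_category_code(cumdose, cutpoints)
  factor(dose_levels()[codes + 1L], levels = dose_levels())
}

dose_levels <- function() c("none", "low", "moderate", "high")

# integer codes 0..3, vectorized over matrices too
dose_category_code <- function(cumdose, cutpoints) {
  codes <- ifelse(cumdose <= 0, 0L,
           ifelse(cumdose <= cutpoints[1], 1L,
           ifelse(cumdose <= cutpoints[2], 2L, 3L)))
  storage.mode(codes) <- "integer"
  codes
}

#' Simulate a cohort under the guarantee-time-bias data-generating process
#'
#' Generates \code{n_subjects} subjects over \code{n_intervals} discrete
#' intervals. A simple random sample of \code{round(N * rate)} subjects is
#' assigned an intended initiation interval W, discrete-uniform on
#' \{1, ..., n_intervals\}. At each interval the subject's dose group is
#' derived from cumulative dose and the event is drawn with
#' \code{\link{event_probability}}; follow-up stops at the first event,
#' otherwise the subject is administratively censored at the last interval.
#' A subject whose event precedes initiation is a realized non-user even if
#' an initiation time was intended.
#'
#' @param config a \code{\link{sim_config}} object.
#' @return an object of class \code{gtb_cohort}: a list with
#'   \describe{
#'     \item{subjects}{one row per subject: \code{subject_id},
#'       \code{intended_user}, \code{initiation_interval} (NA for
#'       non-users), \code{followup_end}, \code{event},
#'       \code{final_dose_category} (category at end of follow-up).}
#'     \item{long}{one row per subject-interval up to \code{followup_end}:
#'       \code{subject_id}, \code{interval}, \code{z1}, \code{z2},
#'       \code{z3}, \code{event_this_interval}.}
#'   }
#' @examples
#' coh <- simulate_cohort(sim_config(n_subjects = 500, seed = 42))
#' table(coh$subjects$final_dose_category)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "gtb_config")) config <- do.call(sim_config, unclass(config))
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  K <- config$n_intervals
  d <- round(n * config$intended_user_rate)

  intended <- rep(FALSE, n)
  W <- rep(NA_integer_, n)
  if (d > 0) {
    intended[sample.int(n, d)] <- TRUE
    W[intended] <- draw_initiation_intervals(d, K)
  }

  # dose-group code matrix: subjects x intervals
  catm <- matrix(0L, n, K)
  if (d > 0) {
    iu <- which(intended)
    exposed <- outer(W[iu], seq_len(K), function(w, t) pmax(t - w + 1L, 0L))
    catm[iu, ] <- dose_category_code(exposed * config$dose_per_interval,
                                     config$dose_cutpoints)
  }

  eta <- config$beta0 +
    config$beta1 * (catm == 1L) +
    config$beta2 * (catm == 2L) +
    config$beta3 * (catm == 3L)
  p <- stats::plogis(eta)
  u <- matrix(stats::runif(n * K), n, K)
  evm <- u < p
  has_event <- rowSums(evm) > 0
  first_event <- max.col(evm, ties.method = "first")  # 1 when no event; masked below
  followup <- ifelse(has_event, first_event, K)

  final_code <- catm[cbind(seq_len(n), followup)]
  subjects <- data.frame(
    subject_id = seq_len(n),
    intended_user = intended,
    initiation_interval = W,
    followup_end = as.integer(followup),
    event = has_event,
    final_dose_category = factor(dose_levels()[final_code + 1L], levels = dose_levels())
  )

  sid <- rep(seq_len(n), followup)
  tt <- sequence(followup)
  code_long <- catm[cbind(sid, tt)]
  long <- data.frame(
    subject_id = sid,
    interval = as.integer(tt),
    z1 = as.integer(code_long == 1L),
    z2 = as.integer(code_long == 2L),
    z3 = as.integer(code_long == 3L),
    event_this_interval = (tt == followup[sid]) & has_event[sid]
  )

  structure(list(subjects = subjects, long = long, config = config),
            class = "gtb_cohort")
}

#' @export
print.gtb_cohort <- function(x, ...) {
  s <- x$subjects
  cat(sprintf("Simulated cohort: %d subjects, %d events, %d realized drug users\n",
              nrow(s), sum(s$event), sum(s$final_dose_category != "none")))
  print(table(dose = s$final_dose_category, event = s$event))
  invisible(x)
}
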