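#' Baseline-coded (naive) Cox design
#'
#' Attributes each subject's entire follow-up, from time 0, to the dose
#' category attained at the end of follow-up. This is deliberately the
#' guarantee-time-biased design: a subject who reached the high-dose group
#' is treated as high-dose from cohort entry, so the event-free time they
#' had to survive to accumulate that dose is credited to the exposed state.
#'
#' @param subjects the \code{subjects} table from
#'   \code{\link{simulate_cohort}} or \code{\link{read_user_cohort_csv}}.
#' @return data.frame with columns \code{subject_id}, \code{time},
#'   \code{event}, \code{z1}, \code{z2}, \code{z3}, of class
#'   \code{gtb_design}.
#' @export
make_naive_design <- function(subjects) {
  if (is.null(subjects) || nrow(subjects) == 0L)
    stop("empty cohort: the naive design needs at least one subject")
  code <- as.integer(subjects$final_dose_category) - 1L
  out <- data.frame(subject_id = subjects$subject_id,
                    time = as.numeric(subjects$followup_end),
                    event = as.logical(subjects$event),
                    z1 = as.integer(code == 1L),
                    z2 = as.integer(code == 2L),
                    z3 = as.integer(code == 3L))
  structure(out, class = c("gtb_design", "data.frame"), design = "naive")
}

#' Counting-process expansion for time-dependent Cox regression
#'
#' Collapses the per-interval long table into (start, stop] rows with
#' interval-constant dose-group indicators: consecutive intervals in the
#' same dose group are merged into one row. The event indicator is true
#' only on a subject's final row, and person-time is preserved
#' (sum of stop - start equals the subject's follow-up).
#'
#' @param long the \code{long} table from \code{\link{simulate_cohort}}.
#' @return data.frame with columns \code{subject_id}, \code{start},
#'   \code{stop}, \code{z1}, \code{z2}, \code{z3}, \code{event}, of class
#'   \code{gtb_design}.
#' @export
make_counting_process <- function(long) {
  if (is.null(long) || nrow(long) == 0L) stop("empty long table")
  if (anyDuplicated(long[c("subject_id", "interval")]))
    stop("data error: overlapping intervals within a subject")
  ord <- order(long$subject_id, long$interval)
  long <- long[ord, , drop = FALSE]
  if (any(long$z1 + long$z2 + long$z3 > 1L))
    stop("data error: more than one active dose-group indicator in a row")
  new_subj <- c(TRUE, long$subject_id[-1L] != long$subject_id[-nrow(long)])
  gaps <- diff(long$interval)
  if (any(gaps[!new_subj[-1L]] != 1L))
    stop("data error: intervals of a subject must be contiguous")
  code <- long$z1 + 2L * long$z2 + 3L * long$z3
  new_run <- new_subj | c(TRUE, code[-1L] != code[-length(code)])
  run_start <- which(new_run)
  run_end <- c(run_start[-1L] - 1L, nrow(long))
  out <- data.frame(subject_id = long$subject_id[run_start],
                    start = as.numeric(long$interval[run_start] - 1L),
                    stop = as.numeric(long$interval[run_end]),
                    z1 = long$z1[run_start],
                    z2 = long$z2[run_start],
                    z3 = long$z3[run_start],
                    event = long$event_this_interval[run_end])
  structure(out, class = c("gtb_design", "data.frame"), design = "counting_process")
}

#' Landmark design
#'
#' Builds the time-fixed Cox design of a landmark analysis at landmark time
#' \code{tau}: subjects whose follow-up ends at or before \code{tau} (event
#' or censoring) are excluded; the remaining subjects' exposure is frozen at
#' the dose category attained by \code{tau} and the analysis clock restarts
#' at \code{tau} (\code{time = followup_end - tau}).
#'
#' With \code{coding = "category"} (default) exposure is the three
#' cumulative-dose indicators at \code{tau}; with \code{coding = "binary"}
#' a single user/non-user indicator Z(tau) = I(W < tau | T > tau) is used.
#'
#' @param subjects,long tables from \code{\link{simulate_cohort}}.
#' @param tau landmark time, an interval index strictly inside
#'   (0, n_intervals).
#' @param coding \code{"category"} or \code{"binary"}.
#' @return a \code{gtb_design} data.frame in the same layout as
#'   \code{\link{make_naive_design}} (binary coding has a single \code{z}
#'   column instead of \code{z1..z3}).
#' @export
make_landmark_design <- function(subjects, long, tau, coding = c("category", "binary")) {
  coding <- match.arg(coding)
  K <- max(long$interval)
  if (length(tau) != 1L || !is.finite(tau) || tau <= 0 || tau >= K || tau != round(tau))
    stop("'tau' must be an integer landmark time strictly inside (0, n_intervals)")
  keep <- subjects$followup_end > tau
  if (!any(keep)) stop("data error: no subjects survive the landmark time")
  s <- subjects[keep, , drop = FALSE]
  at_tau <- long[long$interval == tau & long$subject_id %in% s$subject_id, , drop = FALSE]
  at_tau <- at_tau[match(s$subject_id, at_tau$subject_id), , drop = FALSE]
  out <- data.frame(subject_id = s$subject_id,
                    time = as.numeric(s$followup_end - tau),
                    event = as.logical(s$event))
  if (coding == "category") {
    out$z1 <- at_tau$z1
    out$z2 <- at_tau$z2
    out$z3 <- at_tau$z3
  } else {
    out$z <- as.integer(at_tau$z1 + at_tau$z2 + at_tau$z3 > 0L)
  }
  structure(out, class = c("gtb_design", "data.frame"),
            design = "landmark", tau = tau, coding = coding)
}

#' Fit a Cox proportional-hazards model to a design
#'
#' Maximizes the Cox partial likelihood over the dose-group coefficients via
#' \code{survival::coxph}. Time-fixed designs (columns \code{time},
#' \code{event}) use \code{Surv(time, event)}; counting-process designs
#' (columns \code{start}, \code{stop}, \code{event}) use
#' \code{Surv(start, stop, event)}. Discrete event times produce heavy
#' ties; Efron's approximation is the default, Breslow is available.
#'
#' A dose group with no exposed rows, or no event while exposed, carries no
#' information about its coefficient (the partial likelihood is monotone in
#' it); such groups are flagged non-estimable and dropped from the model
#' rather than returned as divergent numbers.
#'
#' @param design a \code{gtb_design} data.frame (or any data.frame with the
#'   same columns).
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @param alpha two-sided significance level stored for printing.
#' @return object of class \code{gtb_fit}: a data.frame with one row per
#'   dose group (\code{group}, \code{estimable}, \code{log_hr}, \code{se},
#'   \code{wald_z}, \code{p_value}, \code{hr}) and attributes
#'   \code{n_subjects_used}, \code{n_events_used}, \code{converged}.
#' @examples
#' coh <- simulate_cohort(sim_config(n_subjects = 2000, seed = 3))
#' fit_cox(make_counting_process(coh$long))
#' @export
fit_cox <- function(design, ties = c("efron", "breslow"), alpha = 0.05) {
  ties <- match.arg(ties)
  df <- as.data.frame(design)
  counting <- all(c("start", "stop") %in% names(df))
  zcols <- intersect(c("z1", "z2", "z3", "z"), names(df))
  if (length(zcols) == 0L) stop("design has no exposure columns")
  n_events <- sum(df$event)
  if (n_events == 0L) stop("fit error: design contains no events")

  groups <- if (identical(zcols, "z")) "user" else c("low", "moderate", "high")[match(zcols, c("z1", "z2", "z3"))]
  # estimable: exposed person-time exists, an unexposed contrast exists,
  # and at least one event occurs while exposed
  estimable <- vapply(zcols, function(zc) {
    z <- df[[zc]]
    sum(z) > 0L && sum(z) < nrow(df) && any(df$event & z == 1L)
  }, logical(1))

  res <- data.frame(group = groups, estimable = estimable,
                    log_hr = NA_real_, se = NA_real_, wald_z = NA_real_,
                    p_value = NA_real_, hr = NA_real_,
                    stringsAsFactors = FALSE)
  converged <- TRUE
  use <- zcols[estimable]
  if (length(use) > 0L) {
    surv <- if (counting) "survival::Surv(start, stop, event)" else "survival::Surv(time, event)"
    fml <- stats::as.formula(paste(surv, "~", paste(use, collapse = " + ")))
    fit <- withCallingHandlers(
      survival::coxph(fml, data = df, ties = ties),
      warning = function(w) {
        if (grepl("converge|infinite|beta may be", conditionMessage(w)))
          converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    sm <- summary(fit)$coefficients
    idx <- match(use, rownames(sm))
    rows <- match(use, zcols)
    res$log_hr[rows] <- sm[idx, "coef"]
    res$se[rows] <- sm[idx, "se(coef)"]
    res$wald_z[rows] <- sm[idx, "z"]
    res$p_value[rows] <- sm[idx, "Pr(>|z|)"]
    res$hr[rows] <- exp(sm[idx, "coef"])
    if (anyNA(res$log_hr[rows]) || any(abs(res$log_hr[rows]) > 15, na.rm = TRUE)) {
      bad <- rows[is.na(res$log_hr[rows]) | abs(res$log_hr[rows]) > 15]
      res$estimable[bad] <- FALSE
      res[bad, c("log_hr", "se", "wald_z", "p_value", "hr")] <- NA_real_
    }
  }
  structure(res, class = c("gtb_fit", "data.frame"),
            n_subjects_used = length(unique(df$subject_id)),
            n_events_used = n_events,
            converged = converged, ties = ties, alpha = alpha,
            design = attr(design, "design"))
}

#' @export
print.gtb_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s design, %s ties): %d subjects, %d events%s\n",
              attr(x, "design") %||% "unknown", attr(x, "ties"),
              attr(x, "n_subjects_used"), attr(x, "n_events_used"),
              if (isTRUE(attr(x, "converged"))) "" else " [NOT CONVERGED]"))
  print.data.frame(cbind(x["group"],
                         round(as.data.frame(x)[c("hr", "log_hr", "se", "wald_z", "p_value")], 4),
                         estimable = x$estimable), row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
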