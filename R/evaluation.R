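#' Monte-Carlo scenario specification
#'
#' A scenario is one data-generating configuration replicated many times,
#' each replication analyzed with the requested methods. Per-replication
#' seeds are \code{config$seed + replication index}, so any replication can
#' be regenerated independently.
#'
#' The true per-group hazard ratios implied by the logistic discrete-time
#' model are computed on the grouped-time proportional-hazards scale:
#' \code{HR_g = log(1 - p_g) / log(1 - p_0)} with
#' \code{p_g = plogis(beta0 + beta_g)}. Under the null this is exactly 1.
#'
#' @param config a \code{\link{sim_config}}.
#' @param n_replications number of Monte-Carlo replications (>= 1).
#' @param alpha two-sided significance level for rejection counts.
#' @param methods subset of \code{c("naive_cox", "timedep_cox", "landmark")}.
#' @param landmark_times landmark times used when \code{"landmark"} is
#'   requested; each strictly inside (0, n_intervals).
#' @param true_hr per-group true hazard ratios (low, moderate, high);
#'   default derived from the configuration as above.
#' @param ties tie handling passed to \code{\link{fit_cox}}.
#' @return object of class \code{gtb_scenario_spec}.
#' @export
scenario_spec <- function(config,
                          n_replications = 1000,
                          alpha = 0.05,
                          methods = c("naive_cox", "timedep_cox", "landmark"),
                          landmark_times = c(5, 7),
                          true_hr = NULL,
                          ties = "efron") {
  if (!inherits(config, "gtb_config")) config <- do.call(sim_config, unclass(config))
  if (length(n_replications) != 1L || n_replications < 1 || n_replications != round(n_replications))
    stop("'n_replications' must be a positive integer")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  methods <- match.arg(methods, c("naive_cox", "timedep_cox", "landmark"), several.ok = TRUE)
  if ("landmark" %in% methods) {
    if (any(landmark_times <= 0 | landmark_times >= config$n_intervals))
      stop("'landmark_times' must lie strictly inside (0, n_intervals)")
  } else landmark_times <- numeric(0)
  if (is.null(true_hr)) true_hr <- implied_true_hr(config)
  if (length(true_hr) != 3L || any(true_hr <= 0))
    stop("'true_hr' must be three positive hazard ratios (low, moderate, high)")
  structure(list(config = config, n_replications = as.integer(n_replications),
                 alpha = alpha, methods = methods,
                 landmark_times = landmark_times,
                 true_hr = stats::setNames(as.numeric(true_hr), c("low", "moderate", "high")),
                 ties = ties),
            class = "gtb_scenario_spec")
}

#' True hazard ratios implied by the logistic discrete-time model
#'
#' Maps the per-interval event probabilities to their continuous-time
#' proportional-hazards equivalents: if the per-interval survival is
#' (1 - p_g) = (1 - p_0)^HR, then HR_g = log(1 - p_g) / log(1 - p_0).
#'
#' @param config a \code{\link{sim_config}}.
#' @return named vector of hazard ratios for low, moderate, high.
#' @export
implied_true_hr <- function(config) {
  p0 <- stats::plogis(config$beta0)
  pg <- stats::plogis(config$beta0 + c(config$beta1, config$beta2, config$beta3))
  stats::setNames(log1p(-pg) / log1p(-p0), c("low", "moderate", "high"))
}

method_keys <- function(spec) {
  keys <- character(0)
  if ("naive_cox" %in% spec$methods) keys <- c(keys, "naive_cox")
  if ("timedep_cox" %in% spec$methods) keys <- c(keys, "timedep_cox")
  if ("landmark" %in% spec$methods)
    keys <- c(keys, paste0("landmark_", spec$landmark_times))
  keys
}

#' Run a Monte-Carlo scenario
#'
#' For each replication: simulate a cohort under the configuration (seed =
#' config seed + replication index), build the requested designs, fit each
#' with \code{\link{fit_cox}}, and record the per-group hazard ratio and
#' p-value. Aggregates, per method and dose group, the rejection count at
#' \code{alpha}, the number of estimable replications, the mean hazard
#' ratio, signed bias \code{mean(hr) - true_hr}, absolute bias, and
#' MSE \code{mean((hr - true_hr)^2)}. Replications where a group is
#' non-estimable (e.g. no event while in that group) are excluded from that
#' group's aggregates and counted.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param progress print a progress line every \code{progress} replications
#'   (0 = silent).
#' @return object of class \code{gtb_scenario_result}: a data.frame with one
#'   row per method x dose group (\code{method}, \code{group},
#'   \code{n_estimable}, \code{rejection_count}, \code{mean_hr},
#'   \code{bias}, \code{abs_bias}, \code{mse}) with the spec attached as an
#'   attribute.
#' @examples
#' sp <- scenario_spec(sim_config(n_subjects = 600, seed = 11),
#'                     n_replications = 5, methods = "timedep_cox")
#' run_scenario(sp)
#' @export
run_scenario <- function(spec, progress = 0) {
  stopifnot(inherits(spec, "gtb_scenario_spec"))
  keys <- method_keys(spec)
  R <- spec$n_replications
  groups <- c("low", "moderate", "high")
  hr <- array(NA_real_, dim = c(R, length(keys), 3L),
              dimnames = list(NULL, keys, groups))
  pv <- hr
  for (r in seq_len(R)) {
    cfg <- spec$config
    cfg$seed <- cfg$seed + r
    coh <- simulate_cohort(cfg)
    for (k in keys) {
      design <- switch(sub("_[0-9.]+$", "", k),
        naive_cox = make_naive_design(coh$subjects),
        timedep_cox = make_counting_process(coh$long),
        landmark = make_landmark_design(coh$subjects, coh$long,
                                        tau = as.numeric(sub("^landmark_", "", k))))
      fit <- tryCatch(fit_cox(design, ties = spec$ties, alpha = spec$alpha),
                      error = function(e) NULL)
      if (is.null(fit)) next
      rows <- match(groups, fit$group)
      ok <- !is.na(rows) & fit$estimable[rows]
      hr[r, k, ok] <- fit$hr[rows[ok]]
      pv[r, k, ok] <- fit$p_value[rows[ok]]
    }
    if (progress > 0 && r %% progress == 0)
      message(sprintf("replication %d / %d", r, R))
  }
  out <- expand.grid(group = groups, method = keys,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 2:1]
  agg <- function(fun) mapply(function(k, g) fun(hr[, k, g], pv[, k, g], spec$true_hr[g]),
                              out$method, out$group)
  out$n_estimable <- as.integer(agg(function(h, p, t) sum(!is.na(h))))
  out$rejection_count <- as.integer(agg(function(h, p, t) sum(p < spec$alpha, na.rm = TRUE)))
  out$mean_hr <- agg(function(h, p, t) mean(h, na.rm = TRUE))
  out$bias <- agg(function(h, p, t) mean(h, na.rm = TRUE) - t)
  out$abs_bias <- abs(out$bias)
  out$mse <- agg(function(h, p, t) mean((h - t)^2, na.rm = TRUE))
  flagged <- out$n_estimable == 0L
  if (any(flagged))
    warning(sprintf("group(s) non-estimable in every replication: %s",
                    paste(out$method[flagged], out$group[flagged], sep = "/", collapse = ", ")))
  structure(out, class = c("gtb_scenario_result", "data.frame"),
            spec = spec, all_nonestimable = flagged)
}

#' @export
print.gtb_scenario_result <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Monte-Carlo scenario: %d replications, N = %d, beta0 = %.4f, alpha = %g\n",
              spec$n_replications, spec$config$n_subjects, spec$config$beta0, spec$alpha))
  df <- as.data.frame(x)
  df[c("mean_hr", "bias", "abs_bias", "mse")] <-
    lapply(df[c("mean_hr", "bias", "abs_bias", "mse")], round, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Lay scenario results out as study tables
#'
#' Reshapes one or more scenario results (typically one per beta0 value)
#' into the familiar comparison tables: rejection counts per method for the
#' \code{"type1"} and \code{"power"} layouts, or a (bias, mse) column pair
#' per method for \code{"bias_mse"}. Rows are beta0 label x dose group;
#' columns are one per fitted method (landmark methods one per landmark
#' time).
#'
#' @param results a \code{gtb_scenario_result} or list of them, consistent
#'   in methods and groups.
#' @param layout \code{"type1"}, \code{"power"}, or \code{"bias_mse"}.
#' @return data.frame.
#' @export
tabulate_scenarios <- function(results, layout = c("type1", "power", "bias_mse")) {
  layout <- match.arg(layout)
  if (inherits(results, "gtb_scenario_result")) results <- list(results)
  if (length(results) == 0L) stop("'results' must be nonempty")
  keys <- unique(results[[1]]$method)
  groups <- unique(results[[1]]$group)
  for (res in results)
    if (!identical(unique(res$method), keys) || !identical(unique(res$group), groups))
      stop("layout error: scenario results differ in methods or dose groups")
  rows <- lapply(results, function(res) {
    spec <- attr(res, "spec")
    base <- data.frame(beta0 = sprintf("log(%g)", exp(spec$config$beta0)),
                       dose_group = groups, stringsAsFactors = FALSE)
    for (k in keys) {
      sel <- res[res$method == k, , drop = FALSE]
      sel <- sel[match(groups, sel$group), , drop = FALSE]
      if (layout %in% c("type1", "power")) {
        base[[k]] <- sel$rejection_count
      } else {
        base[[paste0(k, "_bias")]] <- sel$bias
        base[[paste0(k, "_mse")]] <- sel$mse
      }
    }
    base
  })
  do.call(rbind, rows)
}
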