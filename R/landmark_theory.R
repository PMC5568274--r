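# adaptive quadrature over (lower, Inf), split at interior breakpoints so
# kinks/discontinuities of common densities (e.g. uniform endpoints) land on
# panel boundaries
integrate_to_inf <- function(f, lower, abs.tol = 1e-9) {
  breaks <- unique(sort(c(lower, lower + c(1, 2, 5, 10, 20, 50))))
  total <- 0
  for (i in seq_len(length(breaks) - 1L))
    total <- total + stats::integrate(f, breaks[i], breaks[i + 1L],
                                      abs.tol = abs.tol, subdivisions = 200L)$value
  total + stats::integrate(f, breaks[length(breaks)], Inf,
                           abs.tol = abs.tol, subdivisions = 200L)$value
}

#' Parametric specification for the landmark conditional-density theory
#'
#' Holds the distributions of the time to drug initiation W and the times
#' to event in the non-user and user states, T0 and T1, each as a
#' (density, survival) pair of one-argument functions on t >= 0. Supplying
#' the survival functions explicitly avoids numerically integrating the
#' densities for them. A(t) = 1 - G(t), the cdf of W, is derived.
#'
#' On construction each density is checked to integrate to 1 over
#' (0, Inf) within 1e-6 and each survival function is spot-checked to be
#' nonincreasing with S(0) = 1.
#'
#' @param g,G density and survival function of W.
#' @param q0,Q0 density and survival function of T0 (time to event, non-user).
#' @param q1,Q1 density and survival function of T1 (time to event, user).
#' @param check validate the pairs (default TRUE).
#' @return object of class \code{gtb_parametric_spec}.
#' @examples
#' spec <- parametric_spec(
#'   g = function(w) dunif(w, 0, 10), G = function(w) punif(w, 0, 10, lower.tail = FALSE),
#'   q0 = function(t) dexp(t, 0.1),   Q0 = function(t) pexp(t, 0.1, lower.tail = FALSE),
#'   q1 = function(t) dexp(t, 0.1),   Q1 = function(t) pexp(t, 0.1, lower.tail = FALSE))
#' @export
parametric_spec <- function(g, G, q0, Q0, q1, Q1, check = TRUE) {
  spec <- list(g = g, G = G, q0 = q0, Q0 = Q0, q1 = q1, Q1 = Q1,
               A = function(t) 1 - G(t))
  class(spec) <- "gtb_parametric_spec"
  if (check) {
    pairs <- list(W = c("g", "G"), T0 = c("q0", "Q0"), T1 = c("q1", "Q1"))
    for (nm in names(pairs)) {
      dens <- spec[[pairs[[nm]][1]]]
      surv <- spec[[pairs[[nm]][2]]]
      tot <- integrate_to_inf(dens, 0)
      if (abs(tot - 1) > 1e-6)
        stop(sprintf("density for %s integrates to %.8f, not 1", nm, tot))
      grid <- c(0, 0.5, 1, 2, 5, 10, 20)
      sv <- vapply(grid, surv, numeric(1))
      if (abs(sv[1] - 1) > 1e-8 || any(diff(sv) > 1e-10))
        stop(sprintf("survival function for %s must be nonincreasing with S(0) = 1", nm))
    }
  }
  spec
}

landmark_numerator_unexposed <- function(t, tau0, spec) {
  spec$q1(t) * (spec$A(t) - spec$A(tau0)) + spec$G(t) * spec$q0(t)
}

#' Conditional event-time density of the landmark non-user group
#'
#' Density of the event time conditional on Z(tau0) = 0 (no drug initiation
#' by the landmark time, event-free at the landmark):
#' \deqn{f(t | Z(\tau_0)=0) = \frac{q_1(t)[A(t)-A(\tau_0)] + G(t) q_0(t)}
#'   {\int_{\tau_0}^{\infty} \{q_1(x)[A(x)-A(\tau_0)] + G(x) q_0(x)\} dx}}
#' for t > tau0, with A = 1 - G. The normalizing integral over the infinite
#' domain is computed by adaptive quadrature (absolute tolerance 1e-9).
#'
#' @param t evaluation time(s), each > tau0.
#' @param tau0 landmark time > 0.
#' @param spec a \code{\link{parametric_spec}}.
#' @return density value(s).
#' @export
density_unexposed <- function(t, tau0, spec) {
  if (tau0 <= 0) stop("'tau0' must be positive")
  if (any(t <= tau0)) stop("domain error: 't' must exceed the landmark time")
  denom <- integrate_to_inf(function(x) landmark_numerator_unexposed(x, tau0, spec), tau0)
  if (!is.finite(denom) || denom <= 0)
    stop("numerical error: normalizing integral is not finite and positive")
  landmark_numerator_unexposed(t, tau0, spec) / denom
}

#' Conditional event-time density of the landmark drug-user group
#'
#' Density of the event time conditional on Z(tau0) = 1:
#' \eqn{f(t | Z(\tau_0)=1) = q_1(t) / Q_1(\tau_0)} for t > tau0.
#'
#' @inheritParams density_unexposed
#' @return density value(s).
#' @export
density_exposed <- function(t, tau0, spec) {
  if (tau0 <= 0) stop("'tau0' must be positive")
  if (any(t <= tau0)) stop("domain error: 't' must exceed the landmark time")
  Q1tau <- spec$Q1(tau0)
  if (!is.finite(Q1tau) || Q1tau <= .Machine$double.eps)
    stop("degenerate conditioning: Q1(tau0) = 0")
  spec$q1(t) / Q1tau
}

#' Verify the landmark null identity
#'
#' Under the null q0 = q1 the two landmark conditional densities coincide
#' with q0(t) / Q0(tau0) for every initiation distribution g — the identity
#' that makes the landmark comparison valid when the drug has no effect.
#' This evaluates both densities on a grid and returns the maximum absolute
#' discrepancies (it measures, it does not assert).
#'
#' @param spec a \code{\link{parametric_spec}} constructed with q0 = q1.
#' @param tau0 landmark time.
#' @param grid evaluation times > tau0; default 40 points on
#'   (tau0, tau0 + 20].
#' @return named numeric vector: \code{unexposed_vs_exposed} and
#'   \code{exposed_vs_closed_form}, the max absolute differences
#'   |f(t|Z=0) - f(t|Z=1)| and |f(t|Z=1) - q0(t)/Q0(tau0)| over the grid.
#' @export
verify_null_identity <- function(spec, tau0, grid = tau0 + seq(0.5, 20, length.out = 40)) {
  f0 <- density_unexposed(grid, tau0, spec)
  f1 <- density_exposed(grid, tau0, spec)
  closed <- spec$q0(grid) / spec$Q0(tau0)
  c(unexposed_vs_exposed = max(abs(f0 - f1)),
    exposed_vs_closed_form = max(abs(f1 - closed)))
}

#' Tabulate both landmark conditional densities over a grid
#'
#' Convenience for plotting/export: evaluates \code{\link{density_unexposed}}
#' and \code{\link{density_exposed}} over a user grid.
#'
#' @inheritParams verify_null_identity
#' @param grid evaluation times > tau0.
#' @return data.frame with columns \code{t}, \code{f_unexposed},
#'   \code{f_exposed}.
#' @export
tabulate_densities <- function(spec, tau0, grid) {
  data.frame(t = grid,
             f_unexposed = density_unexposed(grid, tau0, spec),
             f_exposed = density_exposed(grid, tau0, spec))
}
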