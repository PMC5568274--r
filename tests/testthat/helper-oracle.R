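# Independent brute-force Cox oracle for a single binary covariate.
# Writes out the partial log-likelihood term by term (Efron or Breslow tie
# handling) and maximizes it by golden-section search; deliberately naive
# and loop-based so it shares no code with fit_cox.
oracle_cox_loglik <- function(beta, start, stop, z, event, ties = "efron") {
  ll <- 0
  for (t in sort(unique(stop[event]))) {
    deaths <- which(event & stop == t)
    at_risk <- which(start < t & stop >= t)
    d <- length(deaths)
    s <- sum(z[deaths])
    risk_sum <- sum(exp(beta * z[at_risk]))
    death_sum <- sum(exp(beta * z[deaths]))
    ll <- ll + beta * s
    for (l in seq_len(d) - 1L) {
      ll <- ll - if (ties == "efron") log(risk_sum - (l / d) * death_sum) else log(risk_sum)
    }
  }
  ll
}

oracle_cox_fit <- function(start, stop, z, event, ties = "efron") {
  stats::optimize(function(b) oracle_cox_loglik(b, start, stop, z, event, ties),
                  interval = c(-20, 20), maximum = TRUE, tol = 1e-10)$maximum
}

# random tiny single-covariate survival dataset (time-fixed) whose partial
# likelihood has an interior maximizer (checked with the oracle itself, so
# the screen stays independent of fit_cox)
random_tiny_dataset <- function(n = sample(3:6, 1)) {
  repeat {
    d <- data.frame(start = 0,
                    stop = sample(1:8, n, replace = TRUE),
                    z = sample(0:1, n, replace = TRUE),
                    event = sample(c(TRUE, TRUE, FALSE), n, replace = TRUE))
    if (!(any(d$event & d$z == 1) && any(d$event & d$z == 0) &&
          sum(d$z) > 0 && sum(d$z) < n)) next
    b <- oracle_cox_fit(d$start, d$stop, d$z, d$event)
    if (abs(b) < 8) return(d)
  }
}

default_null_config <- function(seed = 1L) sim_config(seed = seed)
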