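test_that("naive design attributes full follow-up to the final dose category", {
  coh <- simulate_cohort(sim_config(n_subjects = 1500, seed = 21))
  d <- make_naive_design(coh$subjects)
  expect_identical(nrow(d), nrow(coh$subjects))
  expect_equal(d$time, as.numeric(coh$subjects$followup_end))
  # a realized non-user with an event keeps all-zero indicators
  nu <- coh$subjects$final_dose_category == "none"
  expect_true(all(d$z1[nu] == 0 & d$z2[nu] == 0 & d$z3[nu] == 0))
  # category coding agrees with the dose_category oracle at end of follow-up
  s <- coh$subjects[coh$subjects$intended_user, ]
  cd <- cumulative_dose(s$initiation_interval, s$followup_end, 0.5)
  expect_identical(as.character(s$final_dose_category),
                   as.character(dose_category(cd, c(1.5, 3))))
  expect_error(make_naive_design(coh$subjects[0, ]), "empty")
})

test_that("counting-process expansion merges runs and preserves person-time", {
  # single non-user with event at interval 3
  l <- data.frame(subject_id = 1L, interval = 1:3, z1 = 0L, z2 = 0L, z3 = 0L,
                  event_this_interval = c(FALSE, FALSE, TRUE))
  cp <- make_counting_process(l)
  expect_equal(unname(unlist(cp[1, c("start", "stop", "z1", "z2", "z3")])),
               c(0, 3, 0, 0, 0))
  expect_true(cp$event[1])

  # W = 4, dose 0.5, cutpoints (1.5, 3): category switches at doses 1.5 and 3
  W <- 4L
  cd <- cumulative_dose(W, 1:10, 0.5)
  code <- as.integer(dose_category(cd, c(1.5, 3))) - 1L
  l2 <- data.frame(subject_id = 2L, interval = 1:10,
                   z1 = as.integer(code == 1L), z2 = as.integer(code == 2L),
                   z3 = as.integer(code == 3L), event_this_interval = FALSE)
  cp2 <- make_counting_process(l2)
  expect_equal(cp2$start, c(0, 3, 6, 9))
  expect_equal(cp2$stop, c(3, 6, 9, 10))
  expect_equal(cp2$z1 + 2 * cp2$z2 + 3 * cp2$z3, c(0, 1, 2, 3))
  expect_true(all(!cp2$event))

  # person-time conservation on a full cohort
  coh <- simulate_cohort(sim_config(n_subjects = 1000, seed = 22))
  cp3 <- make_counting_process(coh$long)
  pt <- tapply(cp3$stop - cp3$start, cp3$subject_id, sum)
  expect_equal(as.numeric(pt[as.character(coh$subjects$subject_id)]),
               as.numeric(coh$subjects$followup_end))
  # event only on the final row of event subjects
  expect_identical(sum(cp3$event), sum(coh$subjects$event))

  # overlapping intervals are a data error
  bad <- rbind(l, l[3, ])
  expect_error(make_counting_process(bad), "overlapping")
})

test_that("merged and unmerged counting-process rows give identical fits", {
  coh <- simulate_cohort(sim_config(n_subjects = 3000, seed = 23))
  merged <- make_counting_process(coh$long)
  unmerged <- with(coh$long, data.frame(subject_id = subject_id,
                                        start = interval - 1, stop = interval,
                                        z1 = z1, z2 = z2, z3 = z3,
                                        event = event_this_interval))
  f1 <- fit_cox(merged)
  f2 <- fit_cox(unmerged)
  expect_equal(f1$log_hr, f2$log_hr, tolerance = 1e-8)
  expect_equal(f1$se, f2$se, tolerance = 1e-8)
})

test_that("landmark design excludes pre-landmark follow-up and freezes exposure at tau", {
  coh <- simulate_cohort(sim_config(n_subjects = 2500, seed = 24))
  for (tau in c(5, 7)) {
    d <- make_landmark_design(coh$subjects, coh$long, tau)
    kept <- coh$subjects[match(d$subject_id, coh$subjects$subject_id), ]
    expect_true(all(kept$followup_end > tau))
    expect_equal(d$time, as.numeric(kept$followup_end - tau))
    # frozen exposure equals the dose category at tau via the cumulative-dose oracle
    cd_tau <- cumulative_dose(kept$initiation_interval, tau, 0.5)
    code <- as.integer(dose_category(cd_tau, c(1.5, 3))) - 1L
    expect_identical(d$z1, as.integer(code == 1L))
    expect_identical(d$z3, as.integer(code == 3L))
    # initiation after tau means unexposed at the landmark
    late <- !is.na(kept$initiation_interval) & kept$initiation_interval > tau
    expect_true(all(d$z1[late] == 0 & d$z2[late] == 0 & d$z3[late] == 0))
  }
  expect_error(make_landmark_design(coh$subjects, coh$long, 0), "tau")
  expect_error(make_landmark_design(coh$subjects, coh$long, 10), "tau")
  # binary coding collapses to user / non-user at tau
  b <- make_landmark_design(coh$subjects, coh$long, 5, coding = "binary")
  expect_true(all(b$z %in% 0:1))
})

test_that("fit_cox matches the brute-force partial-likelihood oracle", {
  # spec'd toy: (t=1, event, z=1), (t=2, event, z=0), (t=3, censored, z=1)
  toy <- data.frame(subject_id = 1:3, time = c(1, 2, 3),
                    event = c(TRUE, TRUE, FALSE), z = c(1L, 0L, 1L))
  beta_oracle <- oracle_cox_fit(rep(0, 3), toy$time, toy$z, toy$event)
  f <- fit_cox(toy)
  expect_equal(f$log_hr[1], beta_oracle, tolerance = 1e-6)

  set.seed(31)
  for (i in 1:25) {
    d <- random_tiny_dataset()
    d$subject_id <- seq_len(nrow(d))
    d$time <- d$stop
    for (ties in c("efron", "breslow")) {
      f <- fit_cox(d, ties = ties)
      b <- oracle_cox_fit(d$start, d$stop, d$z, d$event, ties = ties)
      expect_lt(abs(f$log_hr[1] - b), 1e-6,
                label = sprintf("dataset %d (%s ties) |fit - oracle|", i, ties))
    }
  }
})

test_that("oracle agreement extends to counting-process (start, stop] data", {
  # five subjects, three of whom switch exposure mid-follow-up
  d <- data.frame(
    subject_id = c(1L, 1L, 2L, 3L, 3L, 4L, 5L, 5L),
    start = c(0, 2, 0, 0, 2, 0, 0, 3),
    stop  = c(2, 5, 4, 2, 9, 7, 3, 6),
    z     = c(0L, 1L, 0L, 0L, 1L, 0L, 0L, 1L),
    event = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  b <- oracle_cox_fit(d$start, d$stop, d$z, d$event)
  f <- fit_cox(d)
  expect_equal(f$log_hr[1], b, tolerance = 1e-6)
})

test_that("degenerate designs are flagged, not returned as numbers", {
  coh <- simulate_cohort(sim_config(n_subjects = 400, intended_user_rate = 1e-6, seed = 25))
  f <- fit_cox(make_naive_design(coh$subjects))
  expect_true(all(!f$estimable))
  expect_true(all(is.na(f$log_hr)))
  # no events at all is a fit error
  d <- data.frame(subject_id = 1:3, time = c(2, 3, 4), event = FALSE, z = c(0L, 1L, 0L))
  expect_error(fit_cox(d), "no events")
})

test_that("estimates are invariant to subject order", {
  coh <- simulate_cohort(sim_config(n_subjects = 2000, seed = 26))
  cp <- make_counting_process(coh$long)
  set.seed(1)
  f1 <- fit_cox(cp)
  f2 <- fit_cox(cp[sample(nrow(cp)), ])
  expect_equal(f1$log_hr, f2$log_hr, tolerance = 1e-10)
})

test_that("time-dependent Cox is centered at the truth", {
  # null: mean log-HR across replications within 3 Monte-Carlo SEs of 0
  est <- matrix(NA_real_, 60, 3)
  for (r in 1:60) {
    coh <- simulate_cohort(sim_config(n_subjects = 4000, seed = 500 + r))
    f <- fit_cox(make_counting_process(coh$long))
    est[r, ] <- ifelse(f$estimable, f$log_hr, NA)
  }
  for (g in 1:3) {
    x <- est[!is.na(est[, g]), g]
    expect_lt(abs(mean(x)), 3 * sd(x) / sqrt(length(x)))
  }
})
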