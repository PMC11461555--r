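test_that("the status-quo policy is annual screening until diagnosis", {
  sq <- status_quo_policy()
  expect_equal(sq$interval, 4L)
  expect_identical(sq$kind, "fixed-interval")
  expect_error(policy_fixed_interval(0), "interval")
  # exactly one screen per completed in-process year
  p <- short_params(end_age = 40)
  out <- simulate_cohort(p, sq, n = 400, seed = 13)
  f <- out$mean_screens_per_year_by_agebin
  expect_equal(unname(f[f > 0]), rep(1, sum(f > 0)))
  # diagnosed agents are never screened again
  tr <- simulate_cohort(p, sq, n = 400, seed = 13,
                        trajectories = TRUE)$trajectories
  for (d in split(tr, tr$agent)) {
    d <- d[order(d$epoch), ]
    first_trt <- match(TRUE, d$on_treatment)
    if (!is.na(first_trt) && first_trt < nrow(d))
      expect_false(any(d$screened[(first_trt + 1):nrow(d)]))
  }
})

test_that("policy comparison uses common random numbers and exact deltas", {
  p <- short_params(end_age = 40)
  self <- evaluate_policy_pair(p, status_quo_policy(), n = 300, seed = 2)
  expect_equal(unname(self$delta), c(0, 0, 0))
  expect_equal(unname(self$averted), c(0, 0, 0))
  cmp <- evaluate_policy_pair(p, policy_never(), n = 300, seed = 2)
  expect_equal(cmp$delta[["nmb"]],
               cmp$candidate$mean_nmb - cmp$status_quo$mean_nmb)
  expect_equal(cmp$averted[["stage4"]],
               cmp$status_quo$cases_stage4 - cmp$candidate$cases_stage4)
  expect_equal(averted_cases(1200, 800), 400)
})

test_that("common random numbers reduce delta variance versus independent seeds", {
  p <- short_params(end_age = 40)
  pol <- policy_fixed_interval(2L)
  K <- 12
  d_crn <- d_ind <- numeric(K)
  for (k in seq_len(K)) {
    a <- simulate_cohort(p, status_quo_policy(), n = 200, seed = 100 + k)
    b <- simulate_cohort(p, pol, n = 200, seed = 100 + k)
    d_crn[k] <- b$mean_nmb - a$mean_nmb
    b2 <- simulate_cohort(p, pol, n = 200, seed = 500 + k)
    d_ind[k] <- b2$mean_nmb - a$mean_nmb
  }
  expect_lt(stats::var(d_crn), stats::var(d_ind))
})

test_that("national-policy frequencies match a direct counting oracle", {
  # hand-built 3-agent trajectory fixture: agent 1 screens at epochs 1,5,9
  # over 12 in-process epochs; agent 2 screens every epoch but exits during
  # its second year; agent 3 never screens
  mk <- function(agent, epochs, inproc, screened) {
    data.frame(agent = agent, epoch = epochs, in_process = inproc,
               screened = screened)
  }
  fix <- rbind(
    mk(1, 1:12, TRUE, 1:12 %in% c(1, 5, 9)),
    mk(2, 1:8, c(rep(TRUE, 6), FALSE, FALSE),
       c(rep(TRUE, 6), FALSE, FALSE)),
    mk(3, 1:12, TRUE, FALSE)
  )
  np <- approximate_national_policy(fix, start_age = 30)
  # completed in-process years: agent 1 three (1 screen each), agent 2 one
  # (4 screens), agent 3 three (0 screens) => (3*1 + 4 + 0) / 7
  expect_equal(unname(np$frequency["30-40"]), (3 * 1 + 4 + 0) / 7)
  expect_equal(np$first_screen_age, 30)
  expect_equal(np$last_screen_age, 30 + 0.25 * 8)

  # every-epoch screening scores 4/person-year; never-screening scores 0
  p <- short_params(end_age = 40)
  q4 <- simulate_cohort(p, policy_fixed_interval(1L), n = 150, seed = 3,
                        trajectories = TRUE)
  npq <- approximate_national_policy(q4$trajectories)
  expect_equal(unname(npq$frequency["30-40"]), 4)
  expect_equal(npq$frequency,
               q4$mean_screens_per_year_by_agebin)  # two code paths agree
  nv <- simulate_cohort(p, policy_never(), n = 50, seed = 3,
                        trajectories = TRUE)
  npn <- approximate_national_policy(nv$trajectories)
  expect_true(all(npn$frequency == 0))
  expect_true(is.na(npn$first_screen_age) && is.na(npn$last_screen_age))
  expect_error(approximate_national_policy(data.frame()), "empty")
})

test_that("population scaling is linear and reproduces hand arithmetic", {
  zero <- population_scale(list(qalys = rep(0, 4), costs = rep(0, 4),
                                nmb = rep(0, 4)),
                           43e6, 0.03, c(0.2365, 0.2217, 0.3054, 0.2217))
  expect_equal(unname(zero), c(0, 0, 0))
  d <- list(qalys = c(0.05, 0.01, 0.02, 0.02), costs = c(386, -411, 1059, 556),
            nmb = c(7842, 1709, 2320, 2035))
  s <- c(0.25, 0.25, 0.25, 0.25)
  one <- population_scale(d, 1e6, 0.1, s)
  two <- population_scale(d, 2e6, 0.1, s)
  expect_equal(unname(two), 2 * unname(one))
  expect_equal(one[["costs"]], 1e6 * 0.1 * mean(d$costs))
  expect_error(population_scale(d, -1, 0.1, s), "non-negative")
})

test_that("threshold ages scan the sustained screening cadence", {
  # fixture cadence: screens at ages 40..46.5 with gaps 8,8,4,4,2,1 epochs
  prof <- data.frame(age = c(40, 42, 44, 45, 46, 46.25),
                     gap_epochs = c(8, 8, 4, 4, 2, 1))
  got <- screening_threshold_ages(prof)
  # direct scan: earliest age from which all later gaps stay <= threshold
  oracle <- function(e) {
    ok <- vapply(seq_len(nrow(prof)), function(i)
      all(prof$gap_epochs[i:nrow(prof)] <= e), logical(1))
    if (any(ok)) prof$age[which(ok)[1]] else NA_real_
  }
  expect_equal(unname(got),
               vapply(c(2, 1.5, 1, 0.5, 0.25) * 4, oracle, numeric(1)))
  expect_equal(unname(got[c("2yr", "1yr", "0.25yr")]), c(40, 44, 46.25))
  # degenerate policies
  expect_true(all(is.na(screening_threshold_ages(
    data.frame(age = numeric(0), gap_epochs = integer(0))))))
  always <- data.frame(age = 30 + (0:9) / 4, gap_epochs = rep(1, 10))
  expect_equal(unname(screening_threshold_ages(always)), rep(30, 5))
  expect_error(screening_threshold_ages(prof, thresholds = -1), "positive")
})
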