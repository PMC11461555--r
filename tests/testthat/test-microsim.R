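test_that("a quarterly step applies events in order with the printed treatment effect", {
  p0 <- zero_hazard_params()
  a <- new_agent(wm_profile, age = 40, egfr = 80, proteinuria = FALSE)
  b <- natural_history_step(a, p0, t = 1, u = c(0.5, 0.5, 0.5))
  expect_equal(b$age, 40.25)
  b$age <- a$age
  expect_identical(b, a)   # nothing but age moved

  # certain death: no accrual beyond the death rule
  pd <- short_params()
  pd$mortality[] <- 1
  d <- natural_history_step(a, pd, t = 1, u = c(0.5, 0.5, 0.5))
  expect_false(d$alive)
  expect_equal(d$accrued_qalys, 0)
  expect_equal(d$accrued_costs, 0)
  expect_error(natural_history_step(d, pd), "dead")

  # treated eGFR decline: 4.0/yr x 1/4 x (1 - 0.327) per quarter
  pt <- zero_hazard_params()
  pt$egfr_decrement[] <- 4.0
  tr <- new_agent(wm_profile, age = 40, egfr = 80, on_treatment = TRUE)
  tr2 <- natural_history_step(tr, pt, t = 1, u = c(1, 1, 1))
  expect_equal(tr2$egfr, 80 - 4.0 * 0.25 * 0.673)
  un2 <- natural_history_step(new_agent(wm_profile, age = 40, egfr = 80),
                              pt, t = 1, u = c(1, 1, 1))
  expect_equal(un2$egfr, 79)
})

test_that("screening observes the true state with perfect tests and the two-test law otherwise", {
  p <- short_params()
  for (eg in c(95, 75, 45, 20, 5)) for (pr in c(FALSE, TRUE)) {
    a <- new_agent(wm_profile, age = 50, egfr = eg, proteinuria = pr)
    res <- screen_agent(a, p, t = 1, u = c(0.99, 0.99))
    expect_identical(res$observation, state_from_measurements(eg, pr))
    expect_equal(res$agent$screens_taken, 1L)
    expect_equal(res$agent$accrued_costs, p$screening_cost)
  }
  expect_error(screen_agent(new_agent(alive = FALSE), p), "dead")

  # imperfect tests: exact two-test probabilities on a uniform u-grid
  pi <- short_params()
  pi$test_sensitivity <- 0.76
  pi$test_specificity <- 0.96
  u <- (seq_len(100) - 0.5) / 100
  grid <- expand.grid(u1 = u, u2 = u)
  obs_for <- function(agent) mapply(function(u1, u2)
    screen_agent(agent, pi, t = 1, u = c(u1, u2))$observation,
    grid$u1, grid$u2)
  prot_pos <- obs_for(new_agent(wm_profile, egfr = 45, proteinuria = TRUE))
  expect_equal(mean(prot_pos == 1), (1 - 0.76)^2)   # missed: 0.0576
  expect_true(all(prot_pos %in% c(1L, 5L)))
  prot_neg <- obs_for(new_agent(wm_profile, egfr = 45, proteinuria = FALSE))
  expect_equal(mean(prot_neg == 5), 1 - 0.96^2)     # false positive: 0.0784
  expect_true(all(prot_neg %in% c(1L, 5L)))
})

test_that("cohort simulation is deterministic with monotone agent trajectories", {
  p <- short_params(end_age = 40)
  out1 <- simulate_cohort(p, status_quo_policy(), n = 400, seed = 31,
                          trajectories = TRUE)
  out2 <- simulate_cohort(p, status_quo_policy(), n = 400, seed = 31,
                          trajectories = TRUE)
  expect_equal(out1$mean_nmb, out2$mean_nmb)
  expect_identical(out1$agent_screens, out2$agent_screens)
  expect_equal(out1$mean_nmb, p$wtp * out1$mean_qalys - out1$mean_costs)

  tr <- out1$trajectories
  by_agent <- split(tr, tr$agent)
  viol_egfr <- viol_prot <- viol_trt <- viol_dead <- 0
  for (d in by_agent) {
    d <- d[order(d$epoch), ]
    eg <- d$egfr[!is.na(d$egfr)]
    if (any(diff(eg) > 1e-12)) viol_egfr <- viol_egfr + 1
    if (any(diff(d$proteinuria) < 0)) viol_prot <- viol_prot + 1
    if (any(diff(d$on_treatment) < 0)) viol_trt <- viol_trt + 1
    dead <- !d$alive
    if (any(d$disc_qaly[dead] != 0) || any(diff(dead) < 0))
      viol_dead <- viol_dead + 1
  }
  expect_equal(c(viol_egfr, viol_prot, viol_trt, viol_dead), rep(0, 4))
  # never-screen policy takes no screens anywhere
  nv <- simulate_cohort(p, policy_never(), n = 200, seed = 31)
  expect_equal(unname(nv$mean_screens_per_year_by_agebin["30-40"]), 0)
  expect_true(all(nv$agent_screens == 0))
})

test_that("estimated transition tensors are stochastic with absorbing death", {
  sol <- get_short_solution()
  tens <- sol$tensor
  for (arm in list(tens$untreated, tens$treated)) {
    rs <- apply(arm, 3, rowSums)
    expect_true(all(abs(rs - 1) < 1e-12))
    expect_true(all(arm[10, 10, ] == 1))
    # proteinuria never reverts: structural zeros
    expect_true(all(arm[c(2, 3, 5, 7, 9), c(1, 4, 6, 8), ] == 0))
  }
  # degenerate world: identity matrices at every epoch
  p0 <- zero_hazard_params(end_age = 32)
  t0 <- estimate_transition_tensor(p0, n = 300, seed = 4)
  expect_true(all(apply(t0$untreated, 3, identical, diag(10))))
})

test_that("tensor estimates converge to the closed-form onset kernel", {
  p <- onset_only_params(annual_onset = 0.08, end_age = 31)
  tens <- estimate_transition_tensor(p, n = 20000, seed = 6)
  q <- 1 - (1 - 0.08)^(1 / 4)
  for (t in 1:2) {
    visits <- tens$visits_untreated[1, t]
    phat <- sum(tens$untreated[1, 2:3, t])
    se <- sqrt(q * (1 - q) / visits)
    expect_lt(abs(phat - q), 3 * se)
  }
})

test_that("treatment terminal rewards are ordered by severity and sign", {
  sol <- get_short_solution()
  R <- sol$terminal$rewards
  expect_true(all(R[, 10] == 0))
  expect_true(all(R[nrow(R), ] == 0))
  mid <- floor(nrow(R) / 2)
  for (t in c(1, mid)) {
    expect_gte(R[t, 4], R[t, 6])
    expect_gte(R[t, 6], R[t, 8])
    expect_gte(R[t, 5], R[t, 7])
  }
  # with zero willingness-to-pay the reward is minus expected costs
  p0 <- short_params(end_age = 35)
  p0$wtp <- 0
  tz <- estimate_terminal_rewards(p0, n = 500, seed = 3,
                                  method = "montecarlo", epoch_step = 8,
                                  egfr_init = "uniform")
  expect_true(all(tz$rewards <= 0))
  # the Monte-Carlo estimator also honours the severity ordering
  tmc <- estimate_terminal_rewards(short_params(end_age = 35), n = 800,
                                   seed = 3, method = "montecarlo",
                                   epoch_step = 8, egfr_init = "uniform")
  expect_gte(tmc$rewards[1, 4], tmc$rewards[1, 6])
  expect_gte(tmc$rewards[1, 6], tmc$rewards[1, 8])
})

test_that("flat exports cover the tensor and terminal tables", {
  sol <- get_short_solution()
  tab <- tensor_to_table(sol$tensor)
  Tm1 <- dim(sol$tensor$untreated)[3]
  expect_equal(nrow(tab), 2 * Tm1 * 100)
  # spot-check one cell against the array
  row <- tab[tab$epoch == 3 & tab$treatment == "untreated" &
               tab$from == 1 & tab$to == 4, ]
  expect_equal(row$prob, sol$tensor$untreated[1, 4, 3])
  expect_equal(row$visits, sol$tensor$visits_untreated[1, 3])
  tt <- terminal_to_table(sol$terminal)
  expect_equal(nrow(tt), nrow(sol$terminal$rewards) * 10)
  expect_equal(tt$reward[tt$epoch == 5 & tt$state == 4],
               sol$terminal$rewards[5, 4])
})
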