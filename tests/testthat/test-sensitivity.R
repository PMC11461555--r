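test_that("scenario application substitutes exactly the configured levels", {
  base <- default_parameters(wm_profile)
  ident <- apply_scenario(base, scenario_config())
  expect_identical(ident, base)

  us <- apply_scenario(base, scenario_config(cost_set = "USRDS"))
  expect_equal(unname(us$state_costs[4:5] * 4), c(30780, 30780))
  expect_equal(unname(us$state_costs[2:3] * 4), c(28913, 28913))
  expect_equal(unname(us$state_costs[6:9] * 4), rep(41976, 4))
  expect_equal(us$state_costs[1], base$state_costs[1])  # Normal kept

  hc <- apply_scenario(base, scenario_config(cost_set = "Honeycutt"))
  expect_equal(unname(hc$state_costs[2:7] * 4),
               c(1600, 1700, 3500, 3500, 12700, 12700))
  expect_equal(hc$state_costs[8:9], base$state_costs[8:9])  # stage 5 kept

  dm <- apply_scenario(base, scenario_config(egfr_decrement_multiplier = 1.1))
  expect_equal(dm$egfr_decrement, base$egfr_decrement * 1.1)

  ti <- apply_scenario(base, scenario_config(test_characteristics = "imperfect"))
  expect_equal(c(ti$test_sensitivity, ti$test_specificity), c(0.76, 0.96))

  expect_error(scenario_config(wtp = 60000), "willingness")
  expect_error(scenario_config(cost_set = "other"), "cost")
  # the base object is untouched by scenario application
  expect_identical(base, default_parameters(wm_profile))
})

test_that("scenario suites load from structured text", {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  writeLines(paste0(
    '[{"name": "usrds_low_wtp", "cost_set": "USRDS", "wtp": 50000},',
    ' {"treatment_egfr_reduction": 0.4}]'), path)
  sc <- read_scenarios(path)
  expect_named(sc, c("usrds_low_wtp", "scenario2"))
  expect_equal(sc$usrds_low_wtp$cost_set, "USRDS")
  expect_equal(sc$usrds_low_wtp$wtp, 50000)
  expect_equal(sc$scenario2$treatment_egfr_reduction, 0.4)
  expect_equal(sc$scenario2$cost_set, "base")
  writeLines('[{"cost_set": "bogus"}]', path)
  expect_error(read_scenarios(path), "cost")
})

test_that("willingness-to-pay enters only through the NMB identity", {
  p <- short_params(end_age = 40)
  outs <- lapply(c(50000, 100000, 150000), function(w) {
    pw <- apply_scenario(p, scenario_config(wtp = w))
    pw$end_age <- 40
    simulate_cohort(pw, status_quo_policy(), n = 300, seed = 8)
  })
  # QALY and cost streams are bit-identical across WTP levels
  expect_identical(outs[[1]]$agent_qalys, outs[[3]]$agent_qalys)
  expect_identical(outs[[1]]$agent_costs, outs[[3]]$agent_costs)
  expect_identical(outs[[2]]$agent_costs, outs[[3]]$agent_costs)
  expect_equal(outs[[1]]$mean_nmb,
               50000 * outs[[3]]$mean_qalys - outs[[3]]$mean_costs)
  # QALY-weight scenarios leave costs untouched under common random numbers
  pq <- apply_scenario(p, scenario_config(qaly_weight_set = "alternative"))
  pq$end_age <- 40
  alt <- simulate_cohort(pq, status_quo_policy(), n = 300, seed = 8)
  expect_identical(alt$agent_costs, outs[[3]]$agent_costs)
  expect_false(identical(alt$agent_qalys, outs[[3]]$agent_qalys))
})

test_that("higher treatment effectiveness never hurts under common random numbers", {
  p <- short_params(end_age = 55)
  lo <- apply_scenario(p, scenario_config(treatment_egfr_reduction = 0.20))
  hi <- apply_scenario(p, scenario_config(treatment_egfr_reduction = 0.40))
  lo$end_age <- hi$end_age <- 55
  out_lo <- simulate_cohort(lo, status_quo_policy(), n = 1500, seed = 21)
  out_hi <- simulate_cohort(hi, status_quo_policy(), n = 1500, seed = 21)
  d <- out_hi$agent_qalys - out_lo$agent_qalys
  expect_gt(mean(d), 0)
  # the gain is concentrated in treated agents; the typical agent is unharmed
  expect_gte(stats::median(d), 0)
})

test_that("the simultaneous engine draws levels reproducibly and reports CIs", {
  p <- short_params(end_age = 35)
  res <- run_simultaneous(p, status_quo_policy(), n_reps = 8, seed = 5,
                          n = 40)
  expect_equal(nrow(res$replicates), 16)          # 8 replicates x 2 policies
  expect_equal(sort(unique(res$replicates$replicate)), 1:8)
  expect_true(all(res$summary$ci_qalys >= 0))
  expect_true(all(is.finite(res$summary$mean_nmb)))
  expect_equal(res$incremental_nmb,
               res$summary$mean_nmb[2] - res$summary$mean_nmb[1])
  res2 <- run_simultaneous(p, status_quo_policy(), n_reps = 8, seed = 5,
                           n = 40)
  expect_identical(res$replicates, res2$replicates)
  expect_error(run_simultaneous(p, status_quo_policy(), n_reps = 1), "n_reps")
  # levels drawn from the enumerated sets only
  expect_true(all(res$replicates$cost_set %in%
                    c("base", "USRDS", "Honeycutt")))
  expect_true(all(res$replicates$treatment_egfr_reduction %in%
                    c(0.20, 0.327, 0.40)))
})

test_that("replicate-based confidence intervals cover the long-run mean", {
  p <- short_params(end_age = 35)
  # long-run mean QALYs for the fixed base scenario under annual screening
  big <- simulate_cohort(p, status_quo_policy(), n = 20000, seed = 999)
  truth <- big$mean_qalys
  n_meta <- 100
  n_reps <- 8
  covered <- 0
  for (m in seq_len(n_meta)) {
    reps <- vapply(seq_len(n_reps), function(r)
      simulate_cohort(p, status_quo_policy(), n = 50,
                      seed = 10000 + m * 100 + r)$mean_qalys, numeric(1))
    half <- 1.96 * stats::sd(reps) / sqrt(n_reps)
    if (abs(mean(reps) - truth) <= half) covered <- covered + 1
  }
  expect_gte(covered, 90)
})

test_that("the one-way suite spans every lever with a base row", {
  p <- short_params(end_age = 35)
  suite <- run_one_way_suite(p, policy_fixed_interval(2L), n = 120, seed = 3)
  expect_s3_class(suite, "data.frame")
  expect_equal(nrow(suite), 20)  # 10 scenarios x 2 policies
  expect_true(all(c("base", "wtp_50k", "costs_usrds", "test_imperfect") %in%
                    suite$scenario))
  # WTP-only scenarios reproduce base QALYs and costs exactly
  b <- suite[suite$scenario == "base" & suite$policy == "pomdp", ]
  w <- suite[suite$scenario == "wtp_50k" & suite$policy == "pomdp", ]
  expect_equal(w$mean_qalys, b$mean_qalys)
  expect_equal(w$mean_costs, b$mean_costs)
  expect_false(isTRUE(all.equal(w$mean_nmb, b$mean_nmb)))
})
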