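# enumerated levels of the sensitivity levers
SCENARIO_LEVELS <- list(
  treatment_egfr_reduction = c(0.20, 0.327, 0.40),
  cost_set = c("base", "USRDS", "Honeycutt"),
  egfr_decrement_multiplier = c(1.0, 1.1),
  qaly_weight_set = c("base", "alternative"),
  test_characteristics = c("perfect", "imperfect"),
  wtp = c(50000, 100000, 150000)
)

# annual cost sets (USD/year by state); NA = keep base-case value.
# USRDS aggregates stages 4, 5 and ESRD into one figure, mapped to states
# 6..9; Honeycutt reports no stage-5/ESRD costs, so the base values are kept
# for states 8..9.
COST_SETS <- list(
  USRDS = c(NA, 28913, 28913, 30780, 30780, 41976, 41976, 41976, 41976, 0),
  Honeycutt = c(NA, 1600, 1700, 3500, 3500, 12700, 12700, NA, NA, 0)
)

# alternative utility weights: smaller decrements between successive CKD
# stages than the base set
QALY_SETS <- list(
  alternative = c(0.91, 0.90, 0.89, 0.87, 0.86, 0.81, 0.80, 0.73, 0.72, 0)
)

#' Sensitivity scenario configuration
#'
#' A scenario fixes one level for each uncertain model input: treatment
#' effectiveness on eGFR decline (20\%, 32.7\% base, 40\%), the CKD medical
#' cost set (base, USRDS, Honeycutt), a +10\% eGFR-decrement multiplier,
#' willingness-to-pay ($50k/$100k/$150k per QALY), the QALY weight set, and
#' proteinuria-test characteristics (perfect, or sensitivity 0.76 with
#' specificity 0.96).
#'
#' @param treatment_egfr_reduction One of 0.20, 0.327, 0.40.
#' @param cost_set "base", "USRDS" or "Honeycutt".
#' @param egfr_decrement_multiplier 1.0 or 1.1.
#' @param wtp 50000, 100000 or 150000 USD/QALY.
#' @param qaly_weight_set "base" or "alternative".
#' @param test_characteristics "perfect" or "imperfect" (0.76/0.96).
#' @return A \code{ckd_scenario} object.
#' @export
scenario_config <- function(treatment_egfr_reduction = 0.327,
                            cost_set = "base",
                            egfr_decrement_multiplier = 1.0,
                            wtp = 150000,
                            qaly_weight_set = "base",
                            test_characteristics = "perfect") {
  lv <- SCENARIO_LEVELS
  if (!treatment_egfr_reduction %in% lv$treatment_egfr_reduction)
    stop("unknown treatment effectiveness level")
  if (!cost_set %in% lv$cost_set) stop("unknown cost set")
  if (!egfr_decrement_multiplier %in% lv$egfr_decrement_multiplier)
    stop("unknown eGFR decrement multiplier")
  if (!wtp %in% lv$wtp) stop("unknown willingness-to-pay level")
  if (!qaly_weight_set %in% lv$qaly_weight_set) stop("unknown QALY weight set")
  if (!test_characteristics %in% lv$test_characteristics)
    stop("unknown test characteristics")
  structure(list(
    treatment_egfr_reduction = treatment_egfr_reduction,
    cost_set = cost_set,
    egfr_decrement_multiplier = egfr_decrement_multiplier,
    wtp = wtp,
    qaly_weight_set = qaly_weight_set,
    test_characteristics = test_characteristics
  ), class = "ckd_scenario")
}

#' @export
print.ckd_scenario <- function(x, ...) {
  cat("<scenario>",
      sprintf("trt %.1f%% | costs %s | decrement x%.1f | WTP $%sk | QALY %s | test %s\n",
              100 * x$treatment_egfr_reduction, x$cost_set,
              x$egfr_decrement_multiplier, x$wtp / 1000,
              x$qaly_weight_set, x$test_characteristics))
  invisible(x)
}

#' Apply a sensitivity scenario to a parameter set
#'
#' Returns a copy of \code{base} with the scenario's levels substituted;
#' the base set is never modified, and the all-base scenario returns the
#' input unchanged.
#'
#' @param base A \code{ckd_params}.
#' @param scenario A \code{\link{scenario_config}}.
#' @return A valid \code{ckd_params}.
#' @export
apply_scenario <- function(base, scenario) {
  stopifnot(inherits(base, "ckd_params"), inherits(scenario, "ckd_scenario"))
  p <- base
  p$treatment_egfr_reduction <- scenario$treatment_egfr_reduction
  if (scenario$cost_set != "base") {
    ann <- COST_SETS[[scenario$cost_set]]
    keep <- is.na(ann)
    quarterly <- ann / 4
    quarterly[keep] <- p$state_costs[keep]
    p$state_costs <- quarterly
  }
  p$egfr_decrement <- p$egfr_decrement * scenario$egfr_decrement_multiplier
  p$wtp <- scenario$wtp
  if (scenario$qaly_weight_set != "base")
    p$qaly_weights <- QALY_SETS[[scenario$qaly_weight_set]] / 4
  if (scenario$test_characteristics == "imperfect") {
    p$test_sensitivity <- 0.76
    p$test_specificity <- 0.96
  } else {
    p$test_sensitivity <- 1.0
    p$test_specificity <- 1.0
  }
  validate_parameters(p)
  p
}

#' Read scenario configurations from a structured text file
#'
#' The file is a JSON array of objects whose fields are
#' \code{\link{scenario_config}} arguments; omitted fields take base-case
#' levels. Unknown levels are rejected.
#'
#' @param path File path.
#' @return A named list of \code{ckd_scenario} objects (names from the
#'   optional \code{name} field, else \code{scenario1}, ...).
#' @export
read_scenarios <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(raw, function(x) {
    nm <- x$name
    x$name <- NULL
    do.call(scenario_config, x)
  })
  names(out) <- vapply(seq_along(raw), function(i)
    raw[[i]]$name %||% paste0("scenario", i), character(1))
  out
}

eval_scenario <- function(base, scenario, policy, n, seed, label) {
  params <- apply_scenario(base, scenario)
  cmp <- evaluate_policy_pair(params, policy, n, seed)
  ci_half <- function(x) 1.96 * stats::sd(x) / sqrt(length(x))
  sq <- cmp$status_quo
  cand <- cmp$candidate
  data.frame(
    scenario = label,
    policy = c("status_quo", "pomdp"),
    mean_nmb = c(sq$mean_nmb, cand$mean_nmb),
    mean_costs = c(sq$mean_costs, cand$mean_costs),
    mean_qalys = c(sq$mean_qalys, cand$mean_qalys),
    ci_nmb = c(ci_half(params$wtp * sq$agent_qalys - sq$agent_costs),
               ci_half(params$wtp * cand$agent_qalys - cand$agent_costs)),
    ci_costs = c(ci_half(sq$agent_costs), ci_half(cand$agent_costs)),
    ci_qalys = c(ci_half(sq$agent_qalys), ci_half(cand$agent_qalys)),
    incremental_nmb = cmp$delta[["nmb"]],
    stringsAsFactors = FALSE
  )
}

#' One-way sensitivity suite
#'
#' Re-evaluates a fixed screening policy (solved once under base-case
#' assumptions, never re-solved) and the status quo in each one-way
#' perturbed world: treatment effectiveness 20\%/40\%, USRDS and Honeycutt
#' cost sets, +10\% eGFR decrements, WTP $50k/$100k, alternative QALY
#' weights, and imperfect proteinuria tests (0.76/0.96). All scenarios share
#' the cohort seed, so natural-history randomness is common across worlds.
#'
#' @param base Base-case \code{ckd_params}.
#' @param policy The fixed candidate \code{ckd_policy}.
#' @param n Agents per arm.
#' @param seed Integer seed.
#' @return A \code{ckd_scenario_suite}: a data frame of per-scenario,
#'   per-policy means, Monte-Carlo 95\% CI half-widths and incremental NMB.
#' @export
run_one_way_suite <- function(base, policy, n = 1000, seed = 1L) {
  scen <- list(
    base = scenario_config(),
    treatment_20 = scenario_config(treatment_egfr_reduction = 0.20),
    treatment_40 = scenario_config(treatment_egfr_reduction = 0.40),
    costs_usrds = scenario_config(cost_set = "USRDS"),
    costs_honeycutt = scenario_config(cost_set = "Honeycutt"),
    decrement_110 = scenario_config(egfr_decrement_multiplier = 1.1),
    wtp_50k = scenario_config(wtp = 50000),
    wtp_100k = scenario_config(wtp = 100000),
    qaly_alternative = scenario_config(qaly_weight_set = "alternative"),
    test_imperfect = scenario_config(test_characteristics = "imperfect")
  )
  rows <- lapply(names(scen), function(nm)
    eval_scenario(base, scen[[nm]], policy, n, seed, nm))
  structure(do.call(rbind, rows), class = c("ckd_scenario_suite",
                                            "data.frame"))
}

#' Simultaneous (probabilistic) sensitivity analysis
#'
#' Draws every lever except willingness-to-pay (fixed at $150,000/QALY for
#' interpretability) uniformly and independently from its level set, once
#' per replicate; simulates both policies per draw; and reports
#' replicate-level outcomes with 95\% confidence intervals from
#' between-replicate variation. The default 72 replicates equal the size of
#' the full level grid (3 x 3 x 2 x 2 x 2).
#'
#' @param base Base-case \code{ckd_params}.
#' @param policy The fixed candidate \code{ckd_policy}.
#' @param n_reps Number of replicates (>= 2 for CIs), default 72.
#' @param seed Integer seed (level draws and cohorts).
#' @param n Agents per replicate per arm.
#' @return A \code{ckd_simultaneous_result}: \code{replicates} (one row per
#'   replicate per policy, with the drawn levels) and \code{summary} (means
#'   and 95\% CIs per policy, and the incremental NMB).
#' @export
run_simultaneous <- function(base, policy, n_reps = 72L, seed = 1L,
                             n = 500L) {
  if (n_reps < 2) stop("n_reps must be >= 2 for confidence intervals")
  lv <- SCENARIO_LEVELS
  draws <- with_local_seed(substream_seed(seed, 0L, 301L), data.frame(
    treatment_egfr_reduction = sample(lv$treatment_egfr_reduction, n_reps,
                                      replace = TRUE),
    cost_set = sample(lv$cost_set, n_reps, replace = TRUE),
    egfr_decrement_multiplier = sample(lv$egfr_decrement_multiplier, n_reps,
                                       replace = TRUE),
    qaly_weight_set = sample(lv$qaly_weight_set, n_reps, replace = TRUE),
    test_characteristics = sample(lv$test_characteristics, n_reps,
                                  replace = TRUE),
    stringsAsFactors = FALSE
  ))
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sc <- scenario_config(
      treatment_egfr_reduction = draws$treatment_egfr_reduction[r],
      cost_set = draws$cost_set[r],
      egfr_decrement_multiplier = draws$egfr_decrement_multiplier[r],
      wtp = 150000,
      qaly_weight_set = draws$qaly_weight_set[r],
      test_characteristics = draws$test_characteristics[r]
    )
    params <- apply_scenario(base, sc)
    rs <- substream_seed(seed, r, 302L)
    cmp <- evaluate_policy_pair(params, policy, n, rs)
    reps[[r]] <- cbind(
      data.frame(replicate = r, policy = c("status_quo", "pomdp"),
                 nmb = c(cmp$status_quo$mean_nmb, cmp$candidate$mean_nmb),
                 costs = c(cmp$status_quo$mean_costs,
                           cmp$candidate$mean_costs),
                 qalys = c(cmp$status_quo$mean_qalys,
                           cmp$candidate$mean_qalys),
                 stringsAsFactors = FALSE),
      draws[r, , drop = FALSE],
      row.names = NULL
    )
  }
  replicates <- do.call(rbind, reps)
  summarize <- function(pol) {
    d <- replicates[replicates$policy == pol, ]
    ci <- function(x) 1.96 * stats::sd(x) / sqrt(length(x))
    data.frame(policy = pol,
               mean_nmb = mean(d$nmb), ci_nmb = ci(d$nmb),
               mean_costs = mean(d$costs), ci_costs = ci(d$costs),
               mean_qalys = mean(d$qalys), ci_qalys = ci(d$qalys),
               stringsAsFactors = FALSE)
  }
  summary <- rbind(summarize("status_quo"), summarize("pomdp"))
  structure(list(replicates = replicates, summary = summary,
                 incremental_nmb = summary$mean_nmb[2] - summary$mean_nmb[1],
                 n_reps = n_reps, n = n, seed = seed),
            class = "ckd_simultaneous_result")
}

#' @export
print.ckd_simultaneous_result <- function(x, ...) {
  cat("<simultaneous sensitivity>", x$n_reps, "replicates x", x$n,
      "agents\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("  incremental NMB $%+.0f\n", x$incremental_nmb))
  invisible(x)
}
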