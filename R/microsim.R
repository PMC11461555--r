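# ---- counter-derived random substreams -------------------------------------
# Every random draw in the microsimulation comes from a substream derived from
# (cohort seed, epoch, purpose) and is indexed by agent, so results are
# independent of iteration order and common random numbers hold across
# policies run with the same seed.

PURPOSE <- c(death = 1L, proteinuria = 2L, esrd = 3L, test1 = 4L, test2 = 5L,
             init_state = 6L, init_egfr = 7L, alt_run = 8L)

substream_seed <- function(seed, epoch, purpose) {
  h <- as.numeric(seed) %% 2147483647
  h <- (h * 48271) %% 2147483647
  as.integer((h + 1009 * as.numeric(epoch) + as.numeric(purpose)) %%
               2147483647)
}

draw_u <- function(seed, epoch, purpose, n) {
  with_local_seed(substream_seed(seed, epoch, purpose),
                  stats::runif(n))
}

# fast vectorized state classification (same mapping as
# state_from_measurements, no input checking)
fast_state <- function(egfr, prot, alive) {
  band <- (egfr < 60) + (egfr < 30) + (egfr < 15)
  p <- as.integer(prot)
  s <- ifelse(band > 0L, 2L * band + 2L + p, 1L + p * (1L + (egfr < 90)))
  s[!alive] <- DEAD_STATE
  as.integer(s)
}

quarterly_prob <- function(p_annual) 1 - (1 - p_annual)^(1 / 4)

# eGFR bands used to initialize agents within a state (finite cap on the
# open-ended normal/CKD1 bands)
EGFR_CAP <- 120
state_egfr_band <- function(state) {
  lo <- c(60, 90, 60, 30, 30, 15, 15, 0, 0, NA)
  hi <- c(EGFR_CAP, EGFR_CAP, 90, 60, 60, 30, 30, 15, 15, NA)
  cbind(lo = lo[state], hi = hi[state])
}

# ---- single-agent interface ------------------------------------------------

#' Create a simulated agent
#'
#' Agents carry the person-level state of the natural-history
#' microsimulation: demographic profile, age, eGFR, proteinuria, treatment
#' and vital status, ESRD flag, and discounted accruals.
#'
#' @param profile A \code{\link{demographic_profile}}.
#' @param age Age in years.
#' @param egfr eGFR in mL/min/1.73m2.
#' @param proteinuria,on_treatment,esrd,alive Logical flags.
#' @return A \code{ckd_agent} object.
#' @export
new_agent <- function(profile = demographic_profile(), age = 30, egfr = 100,
                      proteinuria = FALSE, on_treatment = FALSE,
                      esrd = FALSE, alive = TRUE) {
  structure(list(
    profile = profile, age = age, egfr = egfr, proteinuria = proteinuria,
    on_treatment = on_treatment, esrd = esrd, alive = alive,
    accrued_qalys = 0, accrued_costs = 0, screens_taken = 0L,
    last_observed_state = NA_integer_
  ), class = "ckd_agent")
}

#' One quarterly natural-history transition for a single agent
#'
#' Advances an agent by one 3-month epoch, applying events in the model's
#' fixed order: (1) mortality draw at the quarterly hazard for the current
#' state, reduced by the treatment mortality effect if on treatment; if
#' still alive, (2) eGFR falls by a quarter of the annual decrement for the
#' agent's age band and proteinuria status, reduced by the treatment eGFR
#' effect if on treatment; (3) a proteinuria-negative agent acquires
#' persistent proteinuria with the quarterly onset probability, reduced by
#' the treatment proteinuria effect if on treatment; (4) an agent in CKD
#' stage 5 enters ESRD with the quarterly ESRD hazard; (5) age advances by
#' 0.25 years and the quarter's cost and QALY weight for the resulting state
#' are accrued, discounted by \eqn{\gamma^{t-1}}. A dead agent accrues
#' nothing.
#'
#' @param agent A living \code{\link{new_agent}}.
#' @param params A \code{ckd_params}.
#' @param t Epoch index (used for discounting), default 1.
#' @param u Three uniforms driving the mortality, proteinuria and ESRD
#'   draws; supply degenerate values for deterministic stepping.
#' @return The updated \code{ckd_agent}.
#' @export
natural_history_step <- function(agent, params, t = 1L,
                                 u = stats::runif(3)) {
  stopifnot(inherits(agent, "ckd_agent"))
  if (!agent$alive) stop("cannot step a dead agent")
  band <- age_band_index(agent$age)
  gamma <- quarterly_discount(params$annual_discount)
  s <- fast_state(agent$egfr, agent$proteinuria, TRUE)
  q_death <- quarterly_prob(params$mortality[band, s]) *
    (if (agent$on_treatment) 1 - params$treatment_mortality_reduction else 1)
  if (u[1] < q_death) {
    agent$alive <- FALSE
    agent$age <- agent$age + 0.25
    return(agent)
  }
  dec <- params$egfr_decrement[band, 1L + agent$proteinuria] *
    (if (agent$on_treatment) 1 - params$treatment_egfr_reduction else 1)
  agent$egfr <- max(agent$egfr - dec / 4, 0)
  if (!agent$proteinuria) {
    q_on <- quarterly_prob(params$proteinuria_onset[band]) *
      (if (agent$on_treatment) 1 - params$treatment_proteinuria_reduction
       else 1)
    if (u[2] < q_on) agent$proteinuria <- TRUE
  }
  if (agent$egfr < 15 && !agent$esrd && u[3] < params$esrd_entry)
    agent$esrd <- TRUE
  agent$age <- agent$age + 0.25
  s_post <- fast_state(agent$egfr, agent$proteinuria, TRUE)
  disc <- gamma^(t - 1)
  agent$accrued_qalys <- agent$accrued_qalys +
    disc * params$qaly_weights[s_post]
  agent$accrued_costs <- agent$accrued_costs + disc * params$state_costs[s_post]
  agent
}

#' Screen a single agent
#'
#' Applies the CKD screening procedure. With perfect tests (the base case)
#' the screen is the concurrent proteinuria + eGFR procedure and the
#' observed state equals the agent's true state. With imperfect proteinuria
#' tests the two-test algorithm is used: two proteinuria tests with the
#' given sensitivity/specificity; if at least one is positive the agent's
#' eGFR is measured exactly and the observed state combines the measured
#' eGFR band with the (positive) proteinuria report; if both are negative no
#' eGFR is measured and the agent is reported as state 1 (so low-eGFR
#' agents without a positive proteinuria test are missed). The screening
#' cost is charged, discounted to epoch \code{t}, and the screen counter is
#' incremented.
#'
#' @param agent A living \code{ckd_agent}.
#' @param params A \code{ckd_params}.
#' @param t Epoch index for discounting.
#' @param u Two uniforms driving the two proteinuria tests.
#' @return A list with \code{agent} (updated) and \code{observation}, the
#'   observed state index (1..9).
#' @export
screen_agent <- function(agent, params, t = 1L, u = stats::runif(2)) {
  stopifnot(inherits(agent, "ckd_agent"))
  if (!agent$alive) stop("cannot screen a dead agent")
  gamma <- quarterly_discount(params$annual_discount)
  agent$accrued_costs <- agent$accrued_costs +
    gamma^(t - 1) * params$screening_cost
  agent$screens_taken <- agent$screens_taken + 1L
  se <- params$test_sensitivity
  sp <- params$test_specificity
  if (se == 1 && sp == 1) {
    obs <- fast_state(agent$egfr, agent$proteinuria, TRUE)
  } else {
    p_pos <- if (agent$proteinuria) se else 1 - sp
    any_pos <- (u[1] < p_pos) || (u[2] < p_pos)
    obs <- if (any_pos) fast_state(agent$egfr, TRUE, TRUE) else 1L
  }
  agent$last_observed_state <- obs
  list(agent = agent, observation = obs)
}

# ---- cohort engine ---------------------------------------------------------

# Vectorized engine behind simulate_cohort / estimate_transition_tensor /
# estimate_terminal_rewards. All stochastic inputs are agent-indexed
# substream draws keyed by (seed, epoch, purpose).
run_microsim <- function(params, n, seed, policy = NULL,
                         first_epoch = 1L, treated = FALSE, init = NULL,
                         record_states = FALSE, record_egfr = FALSE,
                         record_trajectories = FALSE) {
  T <- n_epochs(params$start_age, params$end_age)
  gamma <- quarterly_discount(params$annual_discount)
  tmr <- params$treatment_mortality_reduction
  ter <- params$treatment_egfr_reduction
  tpr <- params$treatment_proteinuria_reduction
  se <- params$test_sensitivity
  sp <- params$test_specificity
  perfect <- (se == 1 && sp == 1)

  # initialization: sample states from the initial prevalence and eGFR
  # uniformly within each state's band, unless an explicit init is given
  if (is.null(init)) {
    u_s <- draw_u(seed, 0L, PURPOSE["init_state"], n)
    state0 <- findInterval(u_s, cumsum(params$initial_prevalence)) + 1L
    u_e <- draw_u(seed, 0L, PURPOSE["init_egfr"], n)
    bands <- state_egfr_band(state0)
    egfr <- bands[, "lo"] + u_e * (bands[, "hi"] - bands[, "lo"])
    prot <- state0 %in% PROT_STATES
  } else {
    egfr <- rep_len(init$egfr, n)
    prot <- rep_len(init$proteinuria, n)
  }
  alive <- rep(TRUE, n)
  on_treat <- rep(isTRUE(treated), n)
  esrd <- rep(FALSE, n)
  diagnosed <- rep(FALSE, n)
  anchor <- rep(0L, n)       # last exactly-observed state (0 = initial belief)
  gap <- rep(0L, n)          # epochs since last exact observation
  sgap <- rep(999L, n)       # epochs since last screen
  qalys <- numeric(n)
  costs <- numeric(n)
  screens <- integer(n)
  ever4 <- ever5 <- rep(FALSE, n)

  # per-year-block screening-frequency accounting (completed in-process
  # process-years only; see methods vignette)
  blk_inproc <- integer(n)
  blk_screens <- integer(n)
  bin_time <- numeric(nrow(NATIONAL_BINS))
  bin_screens <- numeric(nrow(NATIONAL_BINS))
  first_screen_epoch <- NA_integer_
  last_screen_epoch <- NA_integer_

  states_rec <- if (record_states)
    matrix(NA_integer_, n, T) else NULL
  if (record_states)
    states_rec[, first_epoch] <- fast_state(egfr, prot, alive)
  egfr_rec <- if (record_egfr) matrix(NA_real_, n, T) else NULL
  if (record_egfr) egfr_rec[, first_epoch] <- egfr
  traj <- if (record_trajectories)
    vector("list", T - first_epoch + 1L) else NULL

  for (t in seq.int(first_epoch, T - 1L)) {
    age <- params$start_age + 0.25 * (t - 1)
    band <- age_band_index(age)
    eligible <- alive & !diagnosed
    screened <- if (is.null(policy)) rep(FALSE, n) else
      policy_screen_decision(policy, t, age, anchor, gap, sgap, eligible)

    # (1) mortality at the quarterly hazard of the current state
    s_now <- fast_state(egfr, prot, alive)
    q_death <- numeric(n)
    ai <- which(alive)
    q_death[ai] <- quarterly_prob(params$mortality[band, s_now[ai]])
    q_death[on_treat] <- q_death[on_treat] * (1 - tmr)
    u1 <- draw_u(seed, t, PURPOSE["death"], n)
    died <- alive & (u1 < q_death)
    alive <- alive & !died

    # (2) eGFR decline
    dec <- params$egfr_decrement[band, 1L + prot]
    dec[on_treat] <- dec[on_treat] * (1 - ter)
    egfr <- ifelse(alive, pmax(egfr - dec / 4, 0), egfr)

    # (3) proteinuria onset (persistent once acquired)
    q_on <- rep(quarterly_prob(params$proteinuria_onset[band]), n)
    q_on[on_treat] <- q_on[on_treat] * (1 - tpr)
    u2 <- draw_u(seed, t, PURPOSE["proteinuria"], n)
    prot <- prot | (alive & !prot & (u2 < q_on))

    # (4) ESRD entry from CKD stage 5
    u3 <- draw_u(seed, t, PURPOSE["esrd"], n)
    esrd <- esrd | (alive & (egfr < 15) & (u3 < params$esrd_entry))

    # (5) accrual on the end-of-quarter state, discounted to process start
    s_post <- fast_state(egfr, prot, alive)
    disc <- gamma^(t - first_epoch)
    qalys <- qalys + disc * ifelse(alive, params$qaly_weights[s_post], 0)
    costs <- costs + disc * ifelse(alive, params$state_costs[s_post], 0) +
      disc * params$screening_cost * screened
    screens <- screens + screened
    ever4 <- ever4 | (alive & egfr < 30)
    ever5 <- ever5 | (alive & egfr < 15)

    # observation: screen results reflect the quarter's progression
    obs <- rep(NA_integer_, n)
    so <- which(screened & alive)
    if (length(so)) {
      if (perfect) {
        obs[so] <- s_post[so]
      } else {
        u4 <- draw_u(seed, t, PURPOSE["test1"], n)
        u5 <- draw_u(seed, t, PURPOSE["test2"], n)
        p_pos <- ifelse(prot[so], se, 1 - sp)
        any_pos <- (u4[so] < p_pos) | (u5[so] < p_pos)
        obs[so] <- ifelse(any_pos, fast_state(egfr[so], TRUE, TRUE), 1L)
      }
      newly <- so[obs[so] %in% TREAT_STATES]
      diagnosed[newly] <- TRUE
      on_treat[newly] <- TRUE
      neg <- so[obs[so] %in% 1:3]
      anchor[neg] <- obs[neg]
      gap[neg] <- -1L  # becomes 0 after the end-of-epoch increment
    }
    gap <- gap + 1L
    sgap <- ifelse(screened, 1L, sgap + 1L)

    # screening-frequency accounting over completed process-years
    blk_inproc <- blk_inproc + eligible
    blk_screens <- blk_screens + screened
    if (any(screened)) {
      if (is.na(first_screen_epoch)) first_screen_epoch <- t
      last_screen_epoch <- t
    }
    if (t %% 4L == 0L) {
      blk_start_age <- params$start_age + 0.25 * (t - 4)
      bin <- national_age_bin(blk_start_age)
      if (!is.na(bin)) {
        complete <- blk_inproc == 4L
        bin_time[bin] <- bin_time[bin] + sum(complete)
        bin_screens[bin] <- bin_screens[bin] + sum(blk_screens[complete])
      }
      blk_inproc[] <- 0L
      blk_screens[] <- 0L
    }

    if (record_states) states_rec[, t + 1L] <- s_post
    if (record_egfr) egfr_rec[, t + 1L] <- ifelse(alive, egfr, NA_real_)
    if (record_trajectories) {
      traj[[t - first_epoch + 1L]] <- data.frame(
        agent = seq_len(n), epoch = t, age = age + 0.25,
        state = s_post, egfr = ifelse(alive, egfr, NA_real_),
        proteinuria = prot, on_treatment = on_treat, esrd = esrd,
        alive = alive, in_process = eligible, screened = screened,
        observation = obs,
        disc_qaly = disc * ifelse(alive, params$qaly_weights[s_post], 0),
        disc_cost = disc * (ifelse(alive, params$state_costs[s_post], 0) +
                              params$screening_cost * screened)
      )
    }
  }

  list(
    n = n, seed = seed, first_epoch = first_epoch, horizon = T,
    qalys = qalys, costs = costs, screens = screens,
    alive = alive, diagnosed = diagnosed, esrd = esrd,
    ever_stage4 = ever4, ever_stage5 = ever5,
    bin_time_years = bin_time, bin_screens = bin_screens,
    first_screen_epoch = first_screen_epoch,
    last_screen_epoch = last_screen_epoch,
    states = states_rec,
    egfr = egfr_rec,
    trajectories = if (record_trajectories)
      do.call(rbind, traj) else NULL
  )
}

#' Simulate a screening policy on a cohort
#'
#' Runs the natural-history microsimulation for \code{n} diagnosed-diabetic
#' agents from age 30 (states drawn from the initial prevalence, eGFR
#' uniform within the state band) under a screening policy. Each quarter the
#' policy decides whether to screen; a screen revealing CKD stage 3 or above
#' (states 4-9) starts treatment and stops further screening, while results
#' of Normal/CKD1/CKD2 update the patient's observable history and screening
#' continues. Health simulation always continues to death or age 85.
#' Deterministic given \code{seed}; two policies run with the same seed see
#' identical natural-history randomness (common random numbers).
#'
#' @param params A \code{ckd_params}.
#' @param policy A \code{ckd_policy}.
#' @param n Number of agents (>= 1).
#' @param seed Integer seed.
#' @param trajectories If \code{TRUE}, attach a one-row-per-agent-quarter
#'   trajectory table.
#' @return A \code{ckd_cohort_outcome}: per-person discounted means
#'   (\code{mean_qalys}, \code{mean_costs}, \code{mean_nmb} with
#'   \code{mean_nmb = wtp * mean_qalys - mean_costs}), case counts per
#'   100,000 (\code{cases_stage4}, \code{cases_stage5}, \code{cases_esrd}),
#'   average annual screening frequency by age bin
#'   (\code{mean_screens_per_year_by_agebin}, computed over completed
#'   in-process process-years) and overall
#'   (\code{overall_screens_per_year}), first/last screening ages, and the
#'   per-agent vectors under \code{agent_qalys}, \code{agent_costs},
#'   \code{agent_screens}.
#' @export
simulate_cohort <- function(params, policy, n, seed = 1L,
                            trajectories = FALSE) {
  stopifnot(inherits(params, "ckd_params"), inherits(policy, "ckd_policy"))
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  sim <- run_microsim(params, n, seed, policy = policy,
                      record_trajectories = trajectories)
  freq <- ifelse(sim$bin_time_years > 0,
                 sim$bin_screens / sim$bin_time_years, 0)
  names(freq) <- NATIONAL_BINS$label
  out <- structure(list(
    n_agents = n,
    mean_qalys = mean(sim$qalys),
    mean_costs = mean(sim$costs),
    mean_nmb = params$wtp * mean(sim$qalys) - mean(sim$costs),
    cases_stage4 = sum(sim$ever_stage4) / n * 1e5,
    cases_stage5 = sum(sim$ever_stage5) / n * 1e5,
    cases_esrd = sum(sim$esrd) / n * 1e5,
    mean_screens_per_year_by_agebin = freq,
    overall_screens_per_year = if (sum(sim$bin_time_years) > 0)
      sum(sim$bin_screens) / sum(sim$bin_time_years) else 0,
    first_screen_age = if (is.na(sim$first_screen_epoch)) NA_real_ else
      epoch_to_age(sim$first_screen_epoch, params$start_age, params$end_age),
    last_screen_age = if (is.na(sim$last_screen_epoch)) NA_real_ else
      epoch_to_age(sim$last_screen_epoch, params$start_age, params$end_age),
    wtp = params$wtp,
    seed = seed,
    policy_kind = policy$kind,
    agent_qalys = sim$qalys,
    agent_costs = sim$costs,
    agent_screens = sim$screens,
    trajectories = sim$trajectories
  ), class = "ckd_cohort_outcome")
  out
}

#' @export
print.ckd_cohort_outcome <- function(x, ...) {
  cat("<cohort outcome>", x$n_agents, "agents |", x$policy_kind, "policy\n")
  cat(sprintf("  mean QALYs %.3f | mean costs $%s | mean NMB $%s\n",
              x$mean_qalys, format(round(x$mean_costs), big.mark = ","),
              format(round(x$mean_nmb), big.mark = ",")))
  cat(sprintf("  cases/100k: stage4 %.0f, stage5 %.0f, ESRD %.0f\n",
              x$cases_stage4, x$cases_stage5, x$cases_esrd))
  cat("  screens/person-year:",
      paste(sprintf("%s=%.2f", names(x$mean_screens_per_year_by_agebin),
                    x$mean_screens_per_year_by_agebin), collapse = ", "),
      "\n")
  invisible(x)
}
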