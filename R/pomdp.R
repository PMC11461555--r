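#' Quarterly discount factor
#'
#' Converts an annual discount rate into the per-quarter weighting factor
#' \eqn{\gamma} satisfying \eqn{\gamma^4 = 1/(1+r)}, so that four quarters of
#' discounting equal one year at rate \code{annual_rate}.
#'
#' @param annual_rate Annual discount rate in [0, 1).
#' @return The per-quarter factor \eqn{\gamma \in (0, 1]}.
#' @examples
#' quarterly_discount(0.03)  # about 0.992638
#' @export
quarterly_discount <- function(annual_rate) {
  if (!is.numeric(annual_rate) || annual_rate < 0 || annual_rate >= 1)
    stop("annual_rate must lie in [0, 1)")
  (1 + annual_rate)^(-1 / 4)
}

#' Net monetary benefit
#'
#' \code{NMB = wtp x QALYs - costs}: health gains valued at the
#' willingness-to-pay threshold, net of costs.
#'
#' @param qalys Quality-adjusted life years.
#' @param costs Costs in USD.
#' @param wtp Willingness-to-pay in USD per QALY (non-negative).
#' @return NMB in USD.
#' @export
nmb <- function(qalys, costs, wtp = 150000) {
  if (any(wtp < 0)) stop("wtp must be non-negative")
  wtp * qalys - costs
}

#' Epoch/age arithmetic
#'
#' Decision epochs are quarters: epoch 1 is age \code{start_age}, epoch
#' \eqn{t} is age \code{start_age + 0.25 (t - 1)}, and the horizon is
#' \eqn{T = 4 (end\_age - start\_age) + 1} (221 for the default ages 30-85,
#' with the final decision at age 84.75 at epoch \eqn{T - 1}).
#'
#' @param t Epoch index in 1..T.
#' @param start_age,end_age Model age range in years.
#' @return \code{epoch_to_age}: age in years; \code{n_epochs}: the horizon T.
#' @examples
#' n_epochs()          # 221
#' epoch_to_age(220)   # 84.75
#' @export
epoch_to_age <- function(t, start_age = 30, end_age = 85) {
  T <- n_epochs(start_age, end_age)
  if (any(t < 1 | t > T)) stop("epoch out of range 1..", T)
  start_age + 0.25 * (t - 1)
}

#' @rdname epoch_to_age
#' @export
n_epochs <- function(start_age = 30, end_age = 85) {
  as.integer(round((end_age - start_age) * 4)) + 1L
}

#' Observation models for screening and waiting
#'
#' Builds the observation-probability matrices of the decision process. Under
#' \emph{Wait} the physician only learns whether the patient is alive or
#' dead: states 1..9 produce "Alive" with probability 1 and the dead state
#' produces "Dead". Under \emph{Screen} with perfect tests (the base case)
#' the observed CKD state equals the true state: a 10 x 10 identity matrix.
#'
#' With imperfect proteinuria tests the screen follows the two-test
#' algorithm: two proteinuria tests are taken and eGFR is measured only if at
#' least one is positive. A proteinuria-positive state is reported in its
#' true eGFR band with probability \eqn{1-(1-se)^2} and otherwise reported as
#' state 1 (both tests falsely negative, eGFR unmeasured). A
#' proteinuria-negative state draws a false positive with probability
#' \eqn{1-sp^2}, in which case it is reported as the proteinuria variant of
#' its eGFR band (state 1, whose band spans 60+, is reported as CKD2,
#' state 3); otherwise it is reported as state 1. This composite matrix is
#' used for evaluation of imperfect testing and for exploratory solving; the
#' base-case policy is solved under perfect observation.
#'
#' @param sensitivity,specificity Per-proteinuria-test operating
#'   characteristics in [0,1] (base case 1, 1).
#' @return A \code{ckd_obsmodel}: list with \code{screen} (10 x 10 matrix
#'   over reported states) and \code{wait} (10 x 2 matrix over Alive/Dead).
#' @examples
#' build_observation_models(1, 1)$screen  # identity
#' @export
build_observation_models <- function(sensitivity = 1, specificity = 1) {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1)
    stop("sensitivity and specificity must lie in [0,1]")
  wait <- matrix(0, N_STATES, 2, dimnames = list(NULL, c("Alive", "Dead")))
  wait[1:9, "Alive"] <- 1
  wait[DEAD_STATE, "Dead"] <- 1

  screen <- matrix(0, N_STATES, N_STATES)
  if (sensitivity == 1 && specificity == 1) {
    diag(screen) <- 1
  } else {
    p_detect <- 1 - (1 - sensitivity)^2   # >=1 of 2 tests positive, prot+
    p_false <- 1 - specificity^2          # >=1 false positive, prot-
    # proteinuria-positive variant of each non-proteinuric state's eGFR band
    prot_variant <- c(3L, NA, NA, 5L, NA, 7L, NA, 9L, NA, NA)
    for (j in 1:9) {
      if (j %in% PROT_STATES) {
        screen[j, j] <- p_detect
        screen[j, 1] <- 1 - p_detect
      } else {
        screen[j, prot_variant[j]] <- p_false
        screen[j, 1] <- 1 - p_false
      }
    }
    screen[1, 1] <- 1 - p_false  # overwrite: diagonal entry is the negative report
  }
  screen[DEAD_STATE, DEAD_STATE] <- 1
  structure(list(screen = screen, wait = wait,
                 sensitivity = sensitivity, specificity = specificity),
            class = "ckd_obsmodel")
}

#' Assemble the screening POMDP
#'
#' Combines a parameter set, an estimated transition tensor and a
#' terminal-reward table into the full decision-process specification
#' \eqn{(S, A, P, O, R)}: ten health states, actions \{Screen, Wait\},
#' quarterly transition matrices for epochs 1..T-1, observation matrices, and
#' rewards. Stage rewards accrue the state's quarterly health value
#' (quarterly QALY weight x willingness-to-pay minus quarterly state cost)
#' under both actions; the screening cost is the only difference between the
#' actions, charged immediately when screening. The dead state accrues
#' nothing.
#'
#' @param params A \code{ckd_params} object.
#' @param tensor A \code{ckd_tensor} from
#'   \code{\link{estimate_transition_tensor}} covering epochs 1..T-1.
#' @param terminal A \code{ckd_terminal} from
#'   \code{\link{estimate_terminal_rewards}} (or a compatible T x 10 matrix)
#'   giving the lump-sum value of starting treatment in states 4..9 at each
#'   epoch, with zeros for Dead.
#' @return A \code{ckd_pomdp} object with elements \code{horizon} (T),
#'   \code{start_age}, \code{transitions} (10 x 10 x (T-1) array, untreated),
#'   \code{observations}, \code{stage_rewards} (10 x 2, columns Wait/Screen),
#'   \code{terminal_rewards} (T x 10 matrix), \code{gamma},
#'   \code{initial_belief}, \code{wtp}.
#' @export
assemble_pomdp <- function(params, tensor, terminal) {
  stopifnot(inherits(params, "ckd_params"))
  T <- n_epochs(params$start_age, params$end_age)
  P <- if (inherits(tensor, "ckd_tensor")) tensor$untreated else tensor
  if (!(is.array(P) && length(dim(P)) == 3 && all(dim(P)[1:2] == N_STATES)))
    stop("transition tensor must be a 10 x 10 x (T-1) array")
  if (dim(P)[3] != T - 1)
    stop("transition tensor covers ", dim(P)[3], " epochs; need T-1 = ", T - 1)
  rs <- apply(P, 3, rowSums)
  if (any(abs(rs - 1) > 1e-8)) stop("non-stochastic transition rows")
  R <- if (inherits(terminal, "ckd_terminal")) terminal$rewards else terminal
  if (!(is.matrix(R) && nrow(R) == T && ncol(R) == N_STATES))
    stop("terminal rewards must be a T x 10 matrix")
  if (any(R[, DEAD_STATE] != 0)) stop("terminal reward for Dead must be 0")

  obs <- build_observation_models(params$test_sensitivity,
                                  params$test_specificity)
  health <- params$qaly_weights * params$wtp - params$state_costs
  health[DEAD_STATE] <- 0
  stage <- cbind(Wait = health, Screen = health - params$screening_cost)
  stage[DEAD_STATE, ] <- 0

  structure(list(
    horizon = T,
    start_age = params$start_age,
    transitions = P,
    observations = obs,
    stage_rewards = stage,
    terminal_rewards = R,
    gamma = quarterly_discount(params$annual_discount),
    initial_belief = params$initial_prevalence,
    wtp = params$wtp,
    screening_cost = params$screening_cost
  ), class = "ckd_pomdp")
}

#' @export
print.ckd_pomdp <- function(x, ...) {
  cat("<ckd_pomdp>", N_STATES, "states | horizon T =", x$horizon,
      sprintf("| ages %g-%g | gamma %.6f\n", x$start_age,
              epoch_to_age(x$horizon, x$start_age,
                           x$start_age + (x$horizon - 1) / 4), x$gamma))
  invisible(x)
}

#' Serialize a POMDP specification
#'
#' Writes/reads the assembled decision process as a versioned structured-text
#' (JSON) document so that solving can run decoupled from simulation.
#'
#' @param pomdp A \code{ckd_pomdp} object.
#' @param path File path.
#' @export
write_pomdp <- function(pomdp, path) {
  stopifnot(inherits(pomdp, "ckd_pomdp"))
  x <- list(
    schema = "ckdscreen-pomdp/1",
    horizon = pomdp$horizon,
    start_age = pomdp$start_age,
    gamma = pomdp$gamma,
    wtp = pomdp$wtp,
    screening_cost = pomdp$screening_cost,
    initial_belief = pomdp$initial_belief,
    stage_rewards = list(wait = unname(pomdp$stage_rewards[, "Wait"]),
                         screen = unname(pomdp$stage_rewards[, "Screen"])),
    sensitivity = pomdp$observations$sensitivity,
    specificity = pomdp$observations$specificity,
    transitions = lapply(seq_len(dim(pomdp$transitions)[3]), function(t)
      lapply(seq_len(N_STATES), function(i)
        unname(pomdp$transitions[i, , t]))),
    terminal_rewards = lapply(seq_len(nrow(pomdp$terminal_rewards)),
                              function(t) unname(pomdp$terminal_rewards[t, ]))
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pomdp
#' @export
read_pomdp <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "ckdscreen-pomdp/1"))
    stop("unrecognized POMDP schema: ", x$schema)
  Tn <- x$horizon
  P <- array(0, c(N_STATES, N_STATES, Tn - 1))
  tr <- x$transitions
  for (t in seq_len(Tn - 1)) {
    if (is.array(tr) && length(dim(tr)) == 3) {
      P[, , t] <- tr[t, , ]
    } else {
      m <- tr[[t]]
      if (is.list(m)) m <- do.call(rbind, m)
      P[, , t] <- as.matrix(m)
    }
  }
  R <- x$terminal_rewards
  if (is.list(R)) R <- do.call(rbind, R)
  R <- unname(as.matrix(R))
  structure(list(
    horizon = as.integer(Tn),
    start_age = x$start_age,
    transitions = P,
    observations = build_observation_models(x$sensitivity, x$specificity),
    stage_rewards = cbind(Wait = x$stage_rewards$wait,
                          Screen = x$stage_rewards$screen),
    terminal_rewards = R,
    gamma = x$gamma,
    initial_belief = x$initial_belief,
    wtp = x$wtp,
    screening_cost = x$screening_cost
  ), class = "ckd_pomdp")
}
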