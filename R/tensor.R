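#' Estimate quarterly transition matrices from the microsimulation
#'
#' Simulates \code{n} untreated and \code{n} treated agents through the full
#' horizon with no screening and tabulates empirical quarterly transition
#' frequencies among the 10 health states for every epoch and treatment
#' status. Rows are normalized to sum to one; the death row is absorbing;
#' transitions that would revert proteinuria are structural zeros (enforced,
#' not merely estimated). Cells whose from-state was visited fewer than
#' \code{min_visits} times at an epoch keep an identity row and are flagged
#' as unobserved.
#'
#' @param params A \code{ckd_params}.
#' @param n Agents per treatment arm (>= 1).
#' @param seed Integer seed.
#' @param min_visits Minimum visits for a row to count as observed.
#' @return A \code{ckd_tensor}: arrays \code{untreated} and \code{treated}
#'   of dimension 10 x 10 x (T-1), visit counts and unobserved flags of
#'   dimension 10 x (T-1) per arm.
#' @export
estimate_transition_tensor <- function(params, n = 10000, seed = 1L,
                                       min_visits = 10L) {
  stopifnot(inherits(params, "ckd_params"))
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  T <- n_epochs(params$start_age, params$end_age)

  count_one <- function(treated, run_seed) {
    sim <- run_microsim(params, n, run_seed, policy = NULL,
                        treated = treated, record_states = TRUE)
    st <- sim$states
    P <- array(0, c(N_STATES, N_STATES, T - 1L))
    visits <- matrix(0L, N_STATES, T - 1L)
    unobserved <- matrix(FALSE, N_STATES, T - 1L)
    # structural zeros: proteinuria never reverts
    nonprot <- c(1L, 4L, 6L, 8L)
    for (t in seq_len(T - 1L)) {
      idx <- (st[, t] - 1L) * N_STATES + st[, t + 1L]
      counts <- matrix(tabulate(idx, N_STATES * N_STATES),
                       N_STATES, N_STATES, byrow = TRUE)
      counts[PROT_STATES, nonprot] <- 0
      counts[DEAD_STATE, ] <- 0
      rs <- rowSums(counts)
      visits[, t] <- as.integer(rs)
      M <- diag(N_STATES)
      ok <- rs >= min_visits
      unobserved[, t] <- !ok
      unobserved[DEAD_STATE, t] <- FALSE
      if (any(ok)) M[ok, ] <- counts[ok, , drop = FALSE] / rs[ok]
      M[DEAD_STATE, ] <- 0
      M[DEAD_STATE, DEAD_STATE] <- 1
      P[, , t] <- M
    }
    list(P = P, visits = visits, unobserved = unobserved)
  }

  u <- count_one(FALSE, seed)
  tr <- count_one(TRUE, substream_seed(seed, 0L, PURPOSE["alt_run"]))
  structure(list(
    untreated = u$P, treated = tr$P,
    visits_untreated = u$visits, visits_treated = tr$visits,
    unobserved_untreated = u$unobserved, unobserved_treated = tr$unobserved,
    n = n, seed = seed, min_visits = as.integer(min_visits)
  ), class = "ckd_tensor")
}

#' @export
print.ckd_tensor <- function(x, ...) {
  cat("<transition tensor> 10 x 10 x", dim(x$untreated)[3],
      "epochs x {untreated, treated} |", x$n, "agents/arm\n")
  cat(sprintf("  unobserved rows (identity-filled): %d untreated, %d treated\n",
              sum(x$unobserved_untreated), sum(x$unobserved_treated)))
  invisible(x)
}

#' Export a transition tensor as a flat table
#'
#' @param tensor A \code{ckd_tensor}.
#' @return Data frame keyed by (epoch, treatment, from, to) with the
#'   transition probability and the from-state visit count.
#' @export
tensor_to_table <- function(tensor) {
  stopifnot(inherits(tensor, "ckd_tensor"))
  Tm1 <- dim(tensor$untreated)[3]
  one <- function(P, visits, label) {
    data.frame(
      epoch = rep(seq_len(Tm1), each = N_STATES * N_STATES),
      treatment = label,
      from = rep(rep(1:N_STATES, each = N_STATES), times = Tm1),
      to = rep(1:N_STATES, times = N_STATES * Tm1),
      prob = as.vector(vapply(seq_len(Tm1),
                              function(t) as.vector(t(P[, , t])),
                              numeric(N_STATES * N_STATES))),
      visits = as.vector(vapply(seq_len(Tm1),
                                function(t) rep(visits[, t],
                                                each = N_STATES),
                                numeric(N_STATES * N_STATES)))
    )
  }
  rbind(one(tensor$untreated, tensor$visits_untreated, "untreated"),
        one(tensor$treated, tensor$visits_treated, "treated"))
}

#' Estimate lump-sum treatment (terminal) rewards
#'
#' The decision process ends when a screen reveals CKD stage 3 or above and
#' treatment begins; the patient then accrues a lump-sum value equal to the
#' expected remaining discounted lifetime net monetary benefit under
#' treatment, measured within the model's age range (the horizon boundary
#' row is zero for all states, and the dead state has value 0 everywhere).
#'
#' Two estimators are provided. \code{method = "markov"} (the default)
#' computes the treated remaining-life value by backward recursion over the
#' microsimulation-estimated \emph{treated} transition matrices:
#' \eqn{R^t(s) = r(s) + \gamma \sum_j P^{trt,t}_{sj} R^{t+1}(j)} with
#' \eqn{r(s)} the quarterly health value (QALY weight x willingness-to-pay
#' minus state cost). Because the same family of estimated matrices drives
#' the decision process's untreated dynamics, treated and untreated
#' prospects are valued on exactly the same footing, which is what makes
#' the screen-versus-wait comparison meaningful.
#'
#' \code{method = "montecarlo"} instead simulates \code{n} treated agents
#' per (grid epoch, initiation state) cell to death or the end age,
#' discounting accruals back to the initiation epoch, and interpolates
#' linearly between grid epochs.
#'
#' With \code{egfr_init = "occupancy"} (the default), the eGFR of agents
#' initialized in a state is resampled from the empirical eGFR distribution
#' of undiagnosed patients occupying that state at that epoch in an
#' untreated natural-history run -- the same occupancy measure that
#' generates the transition tensor, which keeps the lump-sum values
#' consistent with the belief dynamics (a patient detected in CKD 3 has
#' typically just crossed eGFR 60, not the band midpoint).
#' \code{"uniform"} draws eGFR uniformly within the state's band instead;
#' cells with too few occupants always fall back to uniform.
#'
#' @param params A \code{ckd_params}.
#' @param n Agents per (epoch, state) cell (Monte-Carlo method), or agents
#'   per arm when a tensor has to be estimated (Markov method).
#' @param seed Integer seed.
#' @param method "markov" (recursion over the treated transition matrices)
#'   or "montecarlo" (agent-level simulation per cell).
#' @param tensor A \code{ckd_tensor} whose treated matrices the Markov
#'   method should use; estimated internally when omitted.
#' @param epoch_step Grid spacing in epochs (Monte-Carlo method).
#' @param egfr_init "occupancy" or "uniform" initial-eGFR sampling
#'   (Monte-Carlo method).
#' @param occupancy_n Agents in the occupancy run (ignored for "uniform").
#' @return A \code{ckd_terminal}: \code{rewards}, a T x 10 matrix of USD
#'   values (zero for Dead and at the horizon row), states 4..9 filled.
#' @export
estimate_terminal_rewards <- function(params, n = 2000, seed = 1L,
                                      method = c("markov", "montecarlo"),
                                      tensor = NULL,
                                      epoch_step = 4L,
                                      egfr_init = c("occupancy", "uniform"),
                                      occupancy_n = 10000) {
  stopifnot(inherits(params, "ckd_params"))
  method <- match.arg(method)
  egfr_init <- match.arg(egfr_init)
  T <- n_epochs(params$start_age, params$end_age)

  if (method == "markov") {
    if (is.null(tensor))
      tensor <- estimate_transition_tensor(params, n = max(n, 5000),
                                           seed = seed)
    stopifnot(inherits(tensor, "ckd_tensor"))
    Pt <- tensor$treated
    gamma <- quarterly_discount(params$annual_discount)
    r <- params$qaly_weights * params$wtp - params$state_costs
    r[DEAD_STATE] <- 0
    R <- matrix(0, T, N_STATES)
    v <- numeric(N_STATES)             # horizon boundary: zero
    for (t in seq.int(T - 1L, 1L)) {
      v <- r + gamma * as.numeric(Pt[, , t] %*% v)
      v[DEAD_STATE] <- 0
      R[t, TREAT_STATES] <- v[TREAT_STATES]
    }
    return(structure(list(rewards = R, grid = seq_len(T - 1L), n = tensor$n,
                          seed = seed, method = "markov"),
                     class = "ckd_terminal"))
  }

  grid <- unique(c(seq(1L, T - 1L, by = epoch_step), T - 1L))
  R <- matrix(0, T, N_STATES)

  occ <- NULL
  if (egfr_init == "occupancy")
    occ <- run_microsim(params, occupancy_n,
                        substream_seed(seed, 0L, 99L), policy = NULL,
                        record_states = TRUE, record_egfr = TRUE)

  for (s in TREAT_STATES) {
    band <- state_egfr_band(s)
    prot <- s %in% PROT_STATES
    vals <- numeric(length(grid))
    for (gi in seq_along(grid)) {
      t0 <- grid[gi]
      u_e <- draw_u(seed, t0, 100L + s, n)
      egfr0 <- band[, "lo"] + u_e * (band[, "hi"] - band[, "lo"])
      if (!is.null(occ)) {
        pool <- occ$egfr[occ$states[, t0] == s, t0]
        pool <- pool[!is.na(pool)]
        if (length(pool) >= 30)
          egfr0 <- pool[ceiling(u_e * length(pool))]
      }
      init <- list(egfr = egfr0, proteinuria = prot)
      sim <- run_microsim(params, n, substream_seed(seed, t0, 200L + s),
                          policy = NULL, first_epoch = t0, treated = TRUE,
                          init = init)
      vals[gi] <- params$wtp * mean(sim$qalys) - mean(sim$costs)
    }
    R[seq_len(T - 1L), s] <- stats::approx(grid, vals,
                                           xout = seq_len(T - 1L),
                                           rule = 2)$y
  }
  structure(list(rewards = R, grid = grid, n = n, seed = seed,
                 method = "montecarlo", egfr_init = egfr_init),
            class = "ckd_terminal")
}

#' @export
print.ckd_terminal <- function(x, ...) {
  cat("<terminal rewards>", nrow(x$rewards), "epochs x 10 states |",
      length(x$grid), "grid points,", x$n, "agents each\n")
  invisible(x)
}

#' @rdname tensor_to_table
#' @param terminal A \code{ckd_terminal}.
#' @export
terminal_to_table <- function(terminal) {
  stopifnot(inherits(terminal, "ckd_terminal"))
  Tn <- nrow(terminal$rewards)
  data.frame(epoch = rep(seq_len(Tn), times = N_STATES),
             state = rep(1:N_STATES, each = Tn),
             reward = as.vector(terminal$rewards))
}
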