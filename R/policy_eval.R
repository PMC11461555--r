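#' Compare a candidate screening policy with the status quo
#'
#' Simulates the same cohort under two policies with common random numbers
#' (identical seed, hence identical natural-history randomness per agent and
#' quarter) and reports outcomes and their differences. Averted cases follow
#' the convention (cases without the intervention - cases with the
#' intervention) per 100,000 population, with the status-quo arm playing the
#' role of "without".
#'
#' @param params A \code{ckd_params}.
#' @param policy The candidate \code{ckd_policy} (e.g. a solved tree via
#'   \code{\link{policy_from_tree}}).
#' @param n Agents (>= 1).
#' @param seed Integer seed shared by both arms.
#' @param reference The comparator policy, default
#'   \code{\link{status_quo_policy}}.
#' @return A \code{ckd_comparison}: \code{status_quo} and \code{candidate}
#'   cohort outcomes, \code{delta} (candidate minus status quo for NMB,
#'   costs, QALYs) and \code{averted} (status quo minus candidate case
#'   counts per 100,000 for stage 4, stage 5 and ESRD).
#' @export
evaluate_policy_pair <- function(params, policy, n, seed = 1L,
                                 reference = status_quo_policy()) {
  sq <- simulate_cohort(params, reference, n, seed)
  cand <- simulate_cohort(params, policy, n, seed)
  structure(list(
    profile = params$profile,
    status_quo = sq,
    candidate = cand,
    delta = c(nmb = cand$mean_nmb - sq$mean_nmb,
              costs = cand$mean_costs - sq$mean_costs,
              qalys = cand$mean_qalys - sq$mean_qalys),
    averted = c(stage4 = sq$cases_stage4 - cand$cases_stage4,
                stage5 = sq$cases_stage5 - cand$cases_stage5,
                esrd = sq$cases_esrd - cand$cases_esrd),
    n = n, seed = seed
  ), class = "ckd_comparison")
}

#' @export
print.ckd_comparison <- function(x, ...) {
  cat("<policy comparison>", format(x$profile), "|", x$n, "agents\n")
  cat(sprintf("  dNMB $%+.0f | dCosts $%+.0f | dQALYs %+.4f\n",
              x$delta["nmb"], x$delta["costs"], x$delta["qalys"]))
  cat(sprintf("  averted/100k: stage4 %+.0f, stage5 %+.0f, ESRD %+.0f\n",
              x$averted["stage4"], x$averted["stage5"], x$averted["esrd"]))
  invisible(x)
}

#' Averted cases
#'
#' (cases without the intervention - cases with the intervention), both per
#' 100,000 population.
#'
#' @param without,with_ Case counts per 100,000 under the comparator and the
#'   intervention.
#' @return Averted cases per 100,000.
#' @export
averted_cases <- function(without, with_) without - with_

#' Approximate national screening policy from simulated trajectories
#'
#' Reduces a belief-based policy to the guideline form clinicians use:
#' average screens per person-year within 10-year age bins, plus the
#' earliest and latest ages at which any screen occurs. The denominator is
#' in-process person-time -- agents alive, undiagnosed and within the bin --
#' counted over completed process-years (blocks of 4 consecutive epochs all
#' in-process), which makes the annual status-quo policy score exactly 1.
#'
#' @param trajectories A trajectory table as returned by
#'   \code{\link{simulate_cohort}(..., trajectories = TRUE)} (columns
#'   \code{agent}, \code{epoch}, \code{in_process}, \code{screened}), or a
#'   \code{ckd_cohort_outcome} carrying one.
#' @param start_age Age at epoch 1, default 30.
#' @return A \code{ckd_national_policy}: \code{frequency} (screens per
#'   person-year for bins 30-40, 41-50, 51-60, 61-70, 71-80),
#'   \code{first_screen_age}, \code{last_screen_age} (NA when no screening).
#' @export
approximate_national_policy <- function(trajectories, start_age = 30) {
  if (inherits(trajectories, "ckd_cohort_outcome"))
    trajectories <- trajectories$trajectories
  if (is.null(trajectories) || !nrow(trajectories))
    stop("empty trajectory table")
  tr <- trajectories
  block <- (tr$epoch - 1L) %/% 4L
  key <- paste(tr$agent, block)
  inproc <- tapply(tr$in_process, key, sum)
  nobs <- tapply(rep(1L, nrow(tr)), key, sum)
  screens <- tapply(tr$screened, key, sum)
  complete <- inproc == 4L & nobs == 4L
  blk <- as.integer(sub(".* ", "", names(inproc)))
  bin <- national_age_bin(start_age + blk)
  freq <- numeric(nrow(NATIONAL_BINS))
  for (b in seq_len(nrow(NATIONAL_BINS))) {
    sel <- complete & !is.na(bin) & bin == b
    freq[b] <- if (any(sel)) sum(screens[sel]) / sum(sel) else 0
  }
  names(freq) <- NATIONAL_BINS$label
  scr_epochs <- tr$epoch[tr$screened]
  structure(list(
    frequency = freq,
    first_screen_age = if (length(scr_epochs))
      start_age + 0.25 * (min(scr_epochs) - 1) else NA_real_,
    last_screen_age = if (length(scr_epochs))
      start_age + 0.25 * (max(scr_epochs) - 1) else NA_real_
  ), class = "ckd_national_policy")
}

#' @export
print.ckd_national_policy <- function(x, ...) {
  cat("<approximate national policy>\n")
  cat(sprintf("  first screen age %.2f | last screen age %.2f\n",
              x$first_screen_age, x$last_screen_age))
  cat("  screens/person-year:",
      paste(sprintf("%s=%.2f", names(x$frequency), x$frequency),
            collapse = ", "), "\n")
  invisible(x)
}

#' Scale per-person deltas to national population totals
#'
#' Totals = population x diabetic fraction x sum over demographic groups of
#' (group share x per-person delta), applied to QALYs, costs and NMB.
#'
#' @param deltas A list or data frame of per-profile deltas with elements
#'   \code{qalys}, \code{costs}, \code{nmb} (one value per profile, in the
#'   order of \code{shares}); \code{ckd_comparison} objects are accepted.
#' @param population Total population count.
#' @param diabetic_fraction Fraction with diagnosed diabetes.
#' @param shares Population share of each profile (non-negative).
#' @return Named vector with total \code{qalys}, \code{costs} (USD) and
#'   \code{nmb} (USD).
#' @examples
#' # per-person deltas for four demographic groups, 43M people, 3% diabetic
#' population_scale(list(qalys = c(.055, .009, .022, .017),
#'                       costs = c(385, -410, 1058, 557),
#'                       nmb = c(7842, 1709, 2319, 2035)),
#'                  43e6, 0.03, c(0.2365, 0.2217, 0.3054, 0.2217))
#' @export
population_scale <- function(deltas, population, diabetic_fraction, shares) {
  if (population < 0 || diabetic_fraction < 0 || any(shares < 0))
    stop("population, diabetic_fraction and shares must be non-negative")
  if (is.list(deltas) && all(vapply(deltas, inherits, logical(1),
                                    "ckd_comparison")))
    deltas <- list(
      qalys = vapply(deltas, function(d) d$delta[["qalys"]], numeric(1)),
      costs = vapply(deltas, function(d) d$delta[["costs"]], numeric(1)),
      nmb = vapply(deltas, function(d) d$delta[["nmb"]], numeric(1))
    )
  stopifnot(length(deltas$qalys) == length(shares),
            length(deltas$costs) == length(shares),
            length(deltas$nmb) == length(shares))
  k <- population * diabetic_fraction
  c(qalys = k * sum(shares * deltas$qalys),
    costs = k * sum(shares * deltas$costs),
    nmb = k * sum(shares * deltas$nmb))
}

#' Ages at which screening reaches given frequencies
#'
#' For each threshold interval (in years), finds the earliest age at which
#' the policy's recommended inter-screen gap becomes no larger than that
#' interval and stays so for the rest of the screening ages -- the
#' "starts screening at least every X" summary of a policy.
#'
#' @param x A \code{ckd_policy_tree} (the example-individual cadence is
#'   derived via \code{\link{policy_gap_profile}}) or a data frame with
#'   columns \code{age} and \code{gap_epochs}.
#' @param thresholds Intervals in years, default 2, 1.5, 1, 0.5, 0.25.
#' @param start_age Age at epoch 1 when \code{x} is a tree.
#' @return Named numeric vector of ages (NA where the threshold is never
#'   sustained).
#' @export
screening_threshold_ages <- function(x, thresholds = c(2, 1.5, 1, 0.5, 0.25),
                                     start_age = 30) {
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  prof <- if (inherits(x, "ckd_policy_tree"))
    policy_gap_profile(x, start_age) else x
  out <- stats::setNames(rep(NA_real_, length(thresholds)),
                         paste0(thresholds, "yr"))
  if (!nrow(prof)) return(out)
  ord <- order(prof$age)
  gaps <- prof$gap_epochs[ord]
  ages <- prof$age[ord]
  # suffix running maximum: the largest gap at or after each screen
  sufmax <- rev(cummax(rev(gaps)))
  for (i in seq_along(thresholds)) {
    e <- thresholds[i] * 4  # years -> epochs
    hit <- which(sufmax <= e)
    if (length(hit)) out[i] <- ages[hit[1]]
  }
  out
}
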