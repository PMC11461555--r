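#' Screening policies
#'
#' A screening policy is a pure function of the decision epoch and the
#' patient's observable history (last observed state and epochs since the
#' last screen). Three kinds are supported:
#' \itemize{
#'   \item \code{policy_fixed_interval(k)}: screen every \code{k} quarters,
#'     starting at the first decision epoch;
#'   \item \code{status_quo_policy()}: annual screening, i.e. a fixed
#'     interval of 4 quarters -- the comparator used by national guidelines
#'     for diabetics;
#'   \item \code{policy_never()}: no screening;
#'   \item \code{policy_from_tree(tree)}: follow a solved
#'     \code{\link{backward_induction}} policy tree, looking up the action
#'     for the patient's (epoch, last observed state, epochs since screen)
#'     history;
#'   \item \code{policy_age_binned(freq, ...)}: fixed screens-per-year
#'     frequency within each 10-year age bin, the "national policy" form.
#' }
#' All policies stop screening once a screen reveals CKD stage 3 or above
#' (treatment begins) or the patient dies; that stopping rule is enforced by
#' the simulator, not the policy object.
#'
#' @param interval Screening interval in epochs (quarters), >= 1.
#' @return A policy object of class \code{ckd_policy}.
#' @examples
#' status_quo_policy()
#' @export
policy_fixed_interval <- function(interval) {
  interval <- as.integer(interval)
  if (is.na(interval) || interval < 1L) stop("interval must be >= 1 epoch")
  structure(list(kind = "fixed-interval", interval = interval),
            class = c("ckd_policy_interval", "ckd_policy"))
}

#' @rdname policy_fixed_interval
#' @export
status_quo_policy <- function() policy_fixed_interval(4L)

#' @rdname policy_fixed_interval
#' @export
policy_never <- function() {
  structure(list(kind = "never"), class = c("ckd_policy_never", "ckd_policy"))
}

#' @rdname policy_fixed_interval
#' @param tree A \code{ckd_policy_tree} from \code{\link{backward_induction}}.
#' @export
policy_from_tree <- function(tree) {
  stopifnot(inherits(tree, "ckd_policy_tree"))
  structure(list(kind = "pomdp-tree", tree = tree),
            class = c("ckd_policy_tree_policy", "ckd_policy"))
}

#' @rdname policy_fixed_interval
#' @param frequency Screens per year for each age bin 30-40, 41-50, 51-60,
#'   61-70, 71-80; values in [0, 4]. Converted to per-bin fixed intervals of
#'   \code{round(4/frequency)} quarters (0 means never).
#' @param first_age,last_age No screening before/after these ages.
#' @export
policy_age_binned <- function(frequency, first_age = 30, last_age = 85) {
  if (length(frequency) != 5 || any(frequency < 0) || any(frequency > 4))
    stop("frequency must give 5 age bins with values in [0, 4]")
  if (first_age > last_age) stop("first_age must be <= last_age")
  structure(list(kind = "age-binned-frequency", frequency = frequency,
                 first_age = first_age, last_age = last_age),
            class = c("ckd_policy_agebin", "ckd_policy"))
}

#' @export
print.ckd_policy <- function(x, ...) {
  cat("<screening policy>", x$kind)
  if (x$kind == "fixed-interval")
    cat(sprintf(" (every %d quarter%s)", x$interval,
                if (x$interval > 1) "s" else ""))
  if (x$kind == "age-binned-frequency")
    cat(" [", paste(signif(x$frequency, 3), collapse = ", "), "]/yr")
  cat("\n")
  invisible(x)
}

# screening decision for a cohort at epoch t.
# anchor: last observed state (0 = none), gap: epochs since last exact
# observation, eligible: alive and undiagnosed. Returns a logical vector.
policy_screen_decision <- function(policy, t, age, anchor, gap, sgap,
                                   eligible) {
  UseMethod("policy_screen_decision")
}

#' @export
policy_screen_decision.ckd_policy_never <- function(policy, t, age, anchor,
                                                    gap, sgap, eligible) {
  rep(FALSE, length(eligible))
}

#' @export
policy_screen_decision.ckd_policy_interval <- function(policy, t, age, anchor,
                                                       gap, sgap, eligible) {
  eligible & ((t - 1L) %% policy$interval == 0L)
}

#' @export
policy_screen_decision.ckd_policy_agebin <- function(policy, t, age, anchor,
                                                     gap, sgap, eligible) {
  if (age < policy$first_age || age > policy$last_age)
    return(rep(FALSE, length(eligible)))
  bin <- national_age_bin(age)
  if (is.na(bin)) return(rep(FALSE, length(eligible)))
  f <- policy$frequency[bin]
  if (f <= 0) return(rep(FALSE, length(eligible)))
  interval <- max(1L, as.integer(round(4 / f)))
  # sgap counts epochs since the last screen (this policy is belief-free)
  eligible & (sgap >= interval)
}

#' @export
policy_screen_decision.ckd_policy_tree_policy <- function(policy, t, age,
                                                          anchor, gap, sgap,
                                                          eligible) {
  acts <- tree_action_lookup(policy$tree, t, anchor, gap)
  eligible & !is.na(acts) & acts == "Screen"
}

# age bins of the approximate national policy (by bin start ages)
NATIONAL_BINS <- data.frame(
  label = c("30-40", "41-50", "51-60", "61-70", "71-80"),
  lo = c(30, 41, 51, 61, 71),
  hi = c(40, 50, 60, 70, 80)
)

national_age_bin <- function(age) {
  a <- floor(age)
  idx <- rep(NA_integer_, length(age))
  for (b in seq_len(nrow(NATIONAL_BINS)))
    idx[a >= NATIONAL_BINS$lo[b] & a <= NATIONAL_BINS$hi[b]] <- b
  idx
}
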