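#' Health-state vocabulary for the CKD screening model
#'
#' The model tracks ten health states combining CKD stage (defined by eGFR
#' thresholds) with proteinuria status:
#' \tabular{llll}{
#'   index \tab stage  \tab proteinuria \tab eGFR (mL/min/1.73m2) \cr
#'   1 \tab Normal \tab no  \tab >= 60 \cr
#'   2 \tab CKD1   \tab yes \tab >= 90 \cr
#'   3 \tab CKD2   \tab yes \tab 60-89 \cr
#'   4 \tab CKD3   \tab no  \tab 30-59 \cr
#'   5 \tab CKD3   \tab yes \tab 30-59 \cr
#'   6 \tab CKD4   \tab no  \tab 15-29 \cr
#'   7 \tab CKD4   \tab yes \tab 15-29 \cr
#'   8 \tab CKD5   \tab no  \tab < 15  \cr
#'   9 \tab CKD5   \tab yes \tab < 15  \cr
#'   10 \tab Dead  \tab --  \tab --
#' }
#' eGFR bands are half-open on the left boundary of each stage
#' (\code{[15,30)}, \code{[30,60)}, \code{[60,90)}, \code{[90,Inf)}), the
#' standard KDIGO convention, so the (eGFR, proteinuria) to state map is a
#' partition. An eGFR of 60-89 without proteinuria is classified Normal
#' (kidney damage is required for a CKD 1-2 label).
#'
#' @return A data frame with one row per state: \code{index}, \code{stage},
#'   \code{proteinuria} (logical, \code{NA} for Dead), \code{egfr_lo},
#'   \code{egfr_hi}.
#' @export
health_states <- function() {
  data.frame(
    index = 1:10,
    stage = c("Normal", "CKD1", "CKD2", "CKD3", "CKD3", "CKD4", "CKD4",
              "CKD5", "CKD5", "Dead"),
    proteinuria = c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE,
                    NA),
    egfr_lo = c(60, 90, 60, 30, 30, 15, 15, 0, 0, NA),
    egfr_hi = c(Inf, Inf, 90, 60, 60, 30, 30, 15, 15, NA),
    stringsAsFactors = FALSE
  )
}

#' @rdname health_states
#' @export
N_STATES <- 10L

#' @rdname health_states
#' @export
DEAD_STATE <- 10L

# states whose proteinuria flag is TRUE
PROT_STATES <- c(2L, 3L, 5L, 7L, 9L)
# screen results that initiate treatment and stop the decision process
TREAT_STATES <- 4L:9L

#' Classify measurements into a CKD model state
#'
#' Maps an eGFR measurement and proteinuria status onto the 10-state
#' vocabulary of \code{\link{health_states}}. Vectorized; inputs are recycled
#' to a common length.
#'
#' @param egfr eGFR in mL/min/1.73m2; must be non-negative for alive subjects.
#' @param proteinuria logical, persistent proteinuria present.
#' @param alive logical, default \code{TRUE}; dead subjects map to state 10
#'   regardless of the other inputs.
#' @return Integer state index in 1..10.
#' @examples
#' state_from_measurements(95, FALSE)  # 1, Normal
#' state_from_measurements(95, TRUE)   # 2, CKD1
#' state_from_measurements(45, c(FALSE, TRUE))  # 4 and 5, CKD3
#' @export
state_from_measurements <- function(egfr, proteinuria, alive = TRUE) {
  k <- max(length(egfr), length(proteinuria), length(alive))
  egfr <- rep_len(as.numeric(egfr), k)
  proteinuria <- rep_len(as.logical(proteinuria), k)
  alive <- rep_len(as.logical(alive), k)
  if (any(alive & (is.na(egfr) | egfr < 0)))
    stop("negative or missing eGFR for an alive subject")
  out <- rep.int(DEAD_STATE, k)
  a <- which(alive)
  e <- egfr[a]
  p <- proteinuria[a]
  # stage band: 0 = >=60, 1 = [30,60), 2 = [15,30), 3 = [0,15)
  band <- ifelse(e >= 60, 0L, ifelse(e >= 30, 1L, ifelse(e >= 15, 2L, 3L)))
  s <- integer(length(a))
  s[band == 0L & !p] <- 1L
  s[band == 0L & p] <- ifelse(e[band == 0L & p] >= 90, 2L, 3L)
  s[band == 1L] <- 4L + p[band == 1L]
  s[band == 2L] <- 6L + p[band == 2L]
  s[band == 3L] <- 8L + p[band == 3L]
  out[a] <- s
  out
}

#' State attribute helpers
#'
#' @param state integer state index in 1..10.
#' @return \code{state_stage}: the stage label; \code{state_proteinuria}: the
#'   proteinuria flag (\code{NA} for Dead); \code{state_egfr_band}: a
#'   two-column matrix of band endpoints.
#' @keywords internal
state_stage <- function(state) health_states()$stage[state]

#' @rdname state_stage
#' @keywords internal
state_proteinuria <- function(state) health_states()$proteinuria[state]
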