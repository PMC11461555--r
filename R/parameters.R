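#' Demographic profiles
#'
#' The model stratifies by race (White, Black) and gender (Male, Female);
#' the four combinations are the modeled demographic groups.
#'
#' @param race "White" or "Black".
#' @param gender "Male" or "Female".
#' @return A \code{ckd_profile} object (named list).
#' @examples
#' demographic_profile("White", "Male")
#' @export
demographic_profile <- function(race = c("White", "Black"),
                                gender = c("Male", "Female")) {
  race <- match.arg(race)
  gender <- match.arg(gender)
  structure(list(race = race, gender = gender), class = "ckd_profile")
}

#' @rdname demographic_profile
#' @export
all_profiles <- function() {
  list(
    demographic_profile("White", "Male"),
    demographic_profile("Black", "Male"),
    demographic_profile("White", "Female"),
    demographic_profile("Black", "Female")
  )
}

#' @export
format.ckd_profile <- function(x, ...) paste(x$race, x$gender)

#' @export
print.ckd_profile <- function(x, ...) {
  cat("<demographic profile>", format(x), "\n")
  invisible(x)
}

# age-band starts used for all age-varying schedules; the last band covers
# ages 80 up to the model horizon
AGE_BAND_STARTS <- c(30, 40, 50, 60, 70, 80)

age_band_index <- function(age) {
  pmin(findInterval(age, AGE_BAND_STARTS), length(AGE_BAND_STARTS))
}

#' Default model parameters for a demographic group
#'
#' Returns the full natural-history, economic and test-characteristic input
#' set for one race/gender group. Values printed in the published literature are
#' used directly: annual discount 0.03, willingness-to-pay $150,000/QALY,
#' treatment effects of a 32.7\% reduction in annual eGFR decrement, a 55\%
#' reduction in proteinuria progression and a 23\% reduction in mortality,
#' perfect base-case test sensitivity/specificity, ages 30 to 85, and
#' per-state annual costs of $12,505 / $17,049 / $18,263 / $25,048 / $76,153
#' for CKD stages 1 through 5+ESRD. All other schedules (eGFR decrements,
#' proteinuria onset and mortality hazards, QALY weights, initial prevalence,
#' screening cost) are package defaults chosen to be clinically plausible for
#' a diagnosed-diabetic cohort; they are synthetic, not estimates from any
#' survey, and are documented in the methods vignette. Black profiles receive
#' strictly faster progression (larger eGFR decrements, higher proteinuria
#' onset) than White profiles, and male mortality exceeds female mortality.
#'
#' @param profile A \code{\link{demographic_profile}}.
#' @return A \code{ckd_params} object: a named list with elements
#'   \code{profile}, \code{start_age}, \code{end_age}, \code{age_bands},
#'   \code{egfr_decrement} (bands x \{no proteinuria, proteinuria\}, annual
#'   mL/min/1.73m2 per year), \code{proteinuria_onset} (annual probability by
#'   band), \code{mortality} (annual probability, bands x alive states 1..9),
#'   \code{esrd_entry} (quarterly probability from CKD5),
#'   \code{state_costs} (USD per quarter by state), \code{screening_cost},
#'   \code{qaly_weights} (utility per quarter by state),
#'   \code{treatment_egfr_reduction}, \code{treatment_proteinuria_reduction},
#'   \code{treatment_mortality_reduction}, \code{test_sensitivity},
#'   \code{test_specificity}, \code{wtp}, \code{annual_discount},
#'   \code{initial_prevalence}.
#' @examples
#' p <- default_parameters(demographic_profile("White", "Male"))
#' p$wtp
#' @export
default_parameters <- function(profile = demographic_profile()) {
  stopifnot(inherits(profile, "ckd_profile"))
  nb <- length(AGE_BAND_STARTS)
  black <- profile$race == "Black"
  male <- profile$gender == "Male"

  # annual eGFR decrement (mL/min/1.73m2/yr), rising with age; proteinuria
  # accelerates decline; Black progression strictly faster than White
  dec_np <- c(1.0, 1.2, 1.4, 1.7, 2.0, 2.3)
  dec_p <- c(2.0, 2.4, 2.8, 3.2, 3.6, 4.0)
  race_mult <- if (black) 1.25 else 1.0
  sex_mult <- if (male) 1.0 else 0.9
  egfr_decrement <- cbind(
    no_proteinuria = dec_np * race_mult * sex_mult,
    proteinuria = dec_p * race_mult * sex_mult
  )
  rownames(egfr_decrement) <- paste0("band", seq_len(nb))

  # annual proteinuria onset probability by age band
  onset <- c(0.010, 0.015, 0.021, 0.028, 0.035, 0.040)
  if (black) onset <- onset * 1.4

  # annual all-cause mortality for a diabetic cohort: baseline by age band
  # scaled up with CKD severity; male mortality exceeds female
  base_mort <- c(0.003, 0.005, 0.009, 0.017, 0.035, 0.075)
  state_mult <- c(1.00, 1.05, 1.10, 1.35, 1.45, 1.90, 2.10, 3.20, 3.50)
  sexm <- if (male) 1.15 else 0.90
  racem <- if (black) 1.08 else 1.00
  mortality <- pmin(outer(base_mort, state_mult) * sexm * racem, 0.99)
  dimnames(mortality) <- list(paste0("band", seq_len(nb)),
                              paste0("state", 1:9))

  # annual per-state costs (USD); CKD-stage values as printed for stages
  # 1..5+ESRD, Normal-state cost is a package default
  annual_costs <- c(1500, 12505, 17049, 18263, 18263, 25048, 25048,
                    76153, 76153, 0)
  # annual utility weights for a diabetic cohort by CKD state
  annual_qaly <- c(0.90, 0.88, 0.86, 0.82, 0.80, 0.72, 0.70, 0.58, 0.56, 0)

  # initial state prevalence at age 30 (diagnosed diabetics); Black cohorts
  # carry more baseline proteinuria
  if (black) {
    prev <- c(0.870, 0.055, 0.045, 0.013, 0.012, 0.003, 0.002, 0, 0, 0)
  } else {
    prev <- c(0.900, 0.040, 0.035, 0.012, 0.008, 0.003, 0.002, 0, 0, 0)
  }

  params <- structure(list(
    profile = profile,
    start_age = 30,
    end_age = 85,
    age_bands = AGE_BAND_STARTS,
    egfr_decrement = egfr_decrement,
    proteinuria_onset = onset,
    mortality = mortality,
    esrd_entry = 0.05,
    state_costs = annual_costs / 4,
    screening_cost = 60,
    qaly_weights = annual_qaly / 4,
    treatment_egfr_reduction = 0.327,
    treatment_proteinuria_reduction = 0.55,
    treatment_mortality_reduction = 0.23,
    test_sensitivity = 1.0,
    test_specificity = 1.0,
    wtp = 150000,
    annual_discount = 0.03,
    initial_prevalence = prev
  ), class = "ckd_params")
  validate_parameters(params)
  params
}

#' Validate a parameter set
#'
#' Checks every structural invariant of a \code{ckd_params} object: hazards
#' and fractions in [0,1], non-negative costs, quarterly QALY weights in
#' [0, 0.25], eGFR decrement schedules non-negative, non-decreasing in age
#' and at least as large under proteinuria, and an initial prevalence that
#' sums to one with no mass on the dead state.
#'
#' @param params A \code{ckd_params} object.
#' @return Invisibly \code{TRUE}; stops with a message on the first violation.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "ckd_params"))
  p <- params
  chk <- function(ok, msg) if (!all(ok)) stop("invalid parameter set: ", msg)
  chk(p$start_age < p$end_age, "start_age must precede end_age")
  chk(is.matrix(p$egfr_decrement) && ncol(p$egfr_decrement) == 2,
      "egfr_decrement must be a bands x 2 matrix")
  chk(p$egfr_decrement >= 0, "eGFR decrements must be non-negative")
  chk(apply(p$egfr_decrement, 2, function(x) all(diff(x) >= 0)),
      "eGFR decrements must be non-decreasing in age")
  chk(p$egfr_decrement[, 2] >= p$egfr_decrement[, 1],
      "proteinuria decrement must be >= non-proteinuria decrement")
  probs <- c(p$proteinuria_onset, p$mortality, p$esrd_entry,
             p$treatment_egfr_reduction, p$treatment_proteinuria_reduction,
             p$treatment_mortality_reduction, p$test_sensitivity,
             p$test_specificity)
  chk(probs >= 0 & probs <= 1, "hazards and fractions must lie in [0,1]")
  chk(p$annual_discount >= 0 & p$annual_discount < 1,
      "annual discount must lie in [0,1)")
  chk(p$state_costs >= 0 & p$screening_cost >= 0, "costs must be >= 0")
  chk(p$qaly_weights >= 0 & p$qaly_weights <= 0.25,
      "quarterly QALY weights must lie in [0,0.25]")
  chk(length(p$initial_prevalence) == N_STATES, "prevalence must have 10 states")
  chk(p$initial_prevalence >= 0, "prevalence must be non-negative")
  chk(abs(sum(p$initial_prevalence) - 1) < 1e-9, "prevalence must sum to 1")
  chk(p$initial_prevalence[DEAD_STATE] == 0, "no initial mass on Dead")
  invisible(TRUE)
}

#' @export
print.ckd_params <- function(x, ...) {
  cat("<ckd_params>", format(x$profile),
      sprintf("| ages %g-%g | WTP $%s/QALY | discount %.3f\n",
              x$start_age, x$end_age, format(x$wtp, big.mark = ","),
              x$annual_discount))
  cat(sprintf("  treatment effects: eGFR -%.1f%%, proteinuria -%.0f%%, mortality -%.0f%%\n",
              100 * x$treatment_egfr_reduction,
              100 * x$treatment_proteinuria_reduction,
              100 * x$treatment_mortality_reduction))
  cat(sprintf("  test sensitivity/specificity: %.2f/%.2f | screen cost $%g\n",
              x$test_sensitivity, x$test_specificity, x$screening_cost))
  invisible(x)
}

# run code with the global RNG state preserved, seeding a local stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Randomly perturbed parameter sets
#'
#' Generates a structurally valid parameter set by multiplying each default
#' value by an independent factor drawn uniformly from
#' \code{[1 - jitter, 1 + jitter]}, then repairing invariants: probabilities
#' and fractions are clipped to [0,1], quarterly QALY weights to [0,0.25],
#' decrement schedules are made non-decreasing in age (running maximum) and
#' the proteinuria column is raised to at least the non-proteinuria column,
#' and the initial prevalence is renormalized with zero mass on Dead. Used by
#' the test-suite as a generator of admissible model inputs; deterministic
#' given \code{seed}.
#'
#' @param profile A \code{\link{demographic_profile}}.
#' @param seed Integer seed.
#' @param jitter Relative half-width of the perturbation, in [0, 0.5].
#' @return A valid \code{ckd_params} object.
#' @export
sample_parameters <- function(profile = demographic_profile(), seed = 1L,
                              jitter = 0.1) {
  if (!is.numeric(jitter) || jitter < 0 || jitter > 0.5)
    stop("jitter must lie in [0, 0.5]")
  base <- default_parameters(profile)
  if (jitter == 0) return(base)
  with_local_seed(seed, {
    jit <- function(x) x * stats::runif(length(x), 1 - jitter, 1 + jitter)
    p <- base
    p$egfr_decrement[] <- jit(p$egfr_decrement)
    p$egfr_decrement[] <- apply(p$egfr_decrement, 2, cummax)
    p$egfr_decrement[, 2] <- pmax(p$egfr_decrement[, 2], p$egfr_decrement[, 1])
    p$proteinuria_onset <- pmin(pmax(jit(p$proteinuria_onset), 0), 1)
    p$mortality[] <- pmin(pmax(jit(p$mortality), 0), 1)
    p$esrd_entry <- min(max(jit(p$esrd_entry), 0), 1)
    p$state_costs <- pmax(jit(p$state_costs), 0)
    p$screening_cost <- max(jit(p$screening_cost), 0)
    p$qaly_weights <- pmin(pmax(jit(p$qaly_weights), 0), 0.25)
    p$treatment_egfr_reduction <- min(max(jit(p$treatment_egfr_reduction), 0), 1)
    p$treatment_proteinuria_reduction <-
      min(max(jit(p$treatment_proteinuria_reduction), 0), 1)
    p$treatment_mortality_reduction <-
      min(max(jit(p$treatment_mortality_reduction), 0), 1)
    p$wtp <- max(jit(p$wtp), 0)
    p$annual_discount <- min(max(jit(p$annual_discount), 0), 0.999)
    prev <- pmax(jit(p$initial_prevalence), 0)
    prev[DEAD_STATE] <- 0
    p$initial_prevalence <- prev / sum(prev)
    validate_parameters(p)
    p
  })
}

#' Serialize parameter sets
#'
#' \code{write_params}/\code{read_params} store one parameter set per
#' structured-text (JSON) document at full double precision, so that a
#' write/read round trip reproduces the set exactly.
#' \code{params_to_table}/\code{params_from_table} convert the same content
#' to and from a flat table, one row per scalar value keyed by quantity, age
#' band and state, suitable for TSV export.
#'
#' @param params A \code{ckd_params} object.
#' @param path File path.
#' @return \code{read_params} and \code{params_from_table} return a
#'   \code{ckd_params}; \code{params_to_table} returns a data frame with
#'   columns \code{quantity}, \code{age_band}, \code{state}, \code{value}.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "ckd_params"))
  x <- unclass(params)
  x$profile <- unclass(x$profile)
  x$egfr_decrement <- list(
    no_proteinuria = unname(x$egfr_decrement[, 1]),
    proteinuria = unname(x$egfr_decrement[, 2])
  )
  x$mortality <- lapply(seq_len(nrow(params$mortality)),
                        function(i) unname(params$mortality[i, ]))
  names(x$mortality) <- paste0("band", seq_along(x$mortality))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nb <- length(x$age_bands)
  p <- structure(list(
    profile = demographic_profile(x$profile$race, x$profile$gender),
    start_age = x$start_age,
    end_age = x$end_age,
    age_bands = x$age_bands,
    egfr_decrement = cbind(no_proteinuria = x$egfr_decrement$no_proteinuria,
                           proteinuria = x$egfr_decrement$proteinuria),
    proteinuria_onset = x$proteinuria_onset,
    mortality = do.call(rbind, x$mortality),
    esrd_entry = x$esrd_entry,
    state_costs = x$state_costs,
    screening_cost = x$screening_cost,
    qaly_weights = x$qaly_weights,
    treatment_egfr_reduction = x$treatment_egfr_reduction,
    treatment_proteinuria_reduction = x$treatment_proteinuria_reduction,
    treatment_mortality_reduction = x$treatment_mortality_reduction,
    test_sensitivity = x$test_sensitivity,
    test_specificity = x$test_specificity,
    wtp = x$wtp,
    annual_discount = x$annual_discount,
    initial_prevalence = x$initial_prevalence
  ), class = "ckd_params")
  rownames(p$egfr_decrement) <- paste0("band", seq_len(nb))
  dimnames(p$mortality) <- list(paste0("band", seq_len(nb)),
                                paste0("state", 1:9))
  validate_parameters(p)
  p
}

#' @rdname write_params
#' @export
params_to_table <- function(params) {
  stopifnot(inherits(params, "ckd_params"))
  p <- params
  nb <- length(p$age_bands)
  row <- function(quantity, value, age_band = NA_integer_,
                  state = NA_integer_) {
    data.frame(quantity = quantity, age_band = age_band, state = state,
               value = value, stringsAsFactors = FALSE)
  }
  rbind(
    row("race_black", as.numeric(p$profile$race == "Black")),
    row("gender_male", as.numeric(p$profile$gender == "Male")),
    row("start_age", p$start_age),
    row("end_age", p$end_age),
    row("age_band_start", p$age_bands, age_band = seq_len(nb)),
    row("egfr_decrement_no_proteinuria", unname(p$egfr_decrement[, 1]),
        age_band = seq_len(nb)),
    row("egfr_decrement_proteinuria", unname(p$egfr_decrement[, 2]),
        age_band = seq_len(nb)),
    row("proteinuria_onset", p$proteinuria_onset, age_band = seq_len(nb)),
    row("mortality", as.vector(p$mortality),
        age_band = rep(seq_len(nb), times = 9),
        state = rep(1:9, each = nb)),
    row("esrd_entry", p$esrd_entry),
    row("state_cost", p$state_costs, state = 1:10),
    row("screening_cost", p$screening_cost),
    row("qaly_weight", p$qaly_weights, state = 1:10),
    row("treatment_egfr_reduction", p$treatment_egfr_reduction),
    row("treatment_proteinuria_reduction", p$treatment_proteinuria_reduction),
    row("treatment_mortality_reduction", p$treatment_mortality_reduction),
    row("test_sensitivity", p$test_sensitivity),
    row("test_specificity", p$test_specificity),
    row("wtp", p$wtp),
    row("annual_discount", p$annual_discount),
    row("initial_prevalence", p$initial_prevalence, state = 1:10)
  )
}

#' @rdname write_params
#' @param table A data frame as produced by \code{params_to_table}.
#' @export
params_from_table <- function(table) {
  get1 <- function(q) table$value[table$quantity == q]
  getb <- function(q) {
    rows <- table[table$quantity == q, ]
    rows$value[order(rows$age_band)]
  }
  gets <- function(q) {
    rows <- table[table$quantity == q, ]
    rows$value[order(rows$state)]
  }
  nb <- sum(table$quantity == "age_band_start")
  mrows <- table[table$quantity == "mortality", ]
  mort <- matrix(NA_real_, nb, 9)
  mort[cbind(mrows$age_band, mrows$state)] <- mrows$value
  dimnames(mort) <- list(paste0("band", seq_len(nb)), paste0("state", 1:9))
  dec <- cbind(no_proteinuria = getb("egfr_decrement_no_proteinuria"),
               proteinuria = getb("egfr_decrement_proteinuria"))
  rownames(dec) <- paste0("band", seq_len(nb))
  p <- structure(list(
    profile = demographic_profile(
      if (get1("race_black") == 1) "Black" else "White",
      if (get1("gender_male") == 1) "Male" else "Female"),
    start_age = get1("start_age"),
    end_age = get1("end_age"),
    age_bands = getb("age_band_start"),
    egfr_decrement = dec,
    proteinuria_onset = getb("proteinuria_onset"),
    mortality = mort,
    esrd_entry = get1("esrd_entry"),
    state_costs = gets("state_cost"),
    screening_cost = get1("screening_cost"),
    qaly_weights = gets("qaly_weight"),
    treatment_egfr_reduction = get1("treatment_egfr_reduction"),
    treatment_proteinuria_reduction = get1("treatment_proteinuria_reduction"),
    treatment_mortality_reduction = get1("treatment_mortality_reduction"),
    test_sensitivity = get1("test_sensitivity"),
    test_specificity = get1("test_specificity"),
    wtp = get1("wtp"),
    annual_discount = get1("annual_discount"),
    initial_prevalence = gets("initial_prevalence")
  ), class = "ckd_params")
  validate_parameters(p)
  p
}
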