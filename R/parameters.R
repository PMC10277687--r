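# Adverse-event types carried by every parameter set (eight, including
# volume depletion).
AE_TYPES <- c(
  "urinary_tract_infection", "genital_mycotic_infection",
  "acute_renal_failure", "hepatic_injury", "volume_depletion",
  "hypotension", "hypoglycaemia", "bone_fracture"
)

ARMS <- c("intervention", "comparator")

# ---- violation bookkeeping ---------------------------------------------

violations <- function() {
  data.frame(code = character(), location = character(),
             message = character(), stringsAsFactors = FALSE)
}

add_violation <- function(v, code, location, message) {
  rbind(v, data.frame(code = code, location = location, message = message,
                      stringsAsFactors = FALSE))
}

# ---- constructor --------------------------------------------------------

#' Assemble a full model parameter set
#'
#' Bundles every input the simulation needs for both arms: the state space,
#' the cohort definition, per-arm period-specific transition matrices,
#' parametric risk equations (all-cause death, CV death, recurrent hHF,
#' treatment discontinuation), a general-population life table, adverse-event
#' incidences, costs (2021 RM), utilities, and economic settings. Most users
#' will obtain one from [generate_parameter_set()] or [load_parameter_set()]
#' rather than calling this directly.
#'
#' @param state_space An [state_space()] object.
#' @param cohort List: `starting_age` (years), `proportion_male` (fraction),
#'   `initial_distribution` (named probability vector over alive states).
#' @param transitions Per-arm list of periods; each period is a list with
#'   `first` (cycle), `last` (cycle or `NA` for open-ended) and `matrix`
#'   (row-stochastic over alive states).
#' @param survival List with elements `all_cause` and `cv`, each a risk model
#'   (see [risk_model()]).
#' @param hhf Poisson rate model for hospitalisation due to heart failure:
#'   list with `coefficients` on the log monthly-rate scale.
#' @param discontinuation Risk model for time to treatment discontinuation.
#' @param life_table Data frame with columns `age`, `sex` ("male"/"female"),
#'   `monthly_all_cause_q`, `monthly_cv_q`.
#' @param ae List with `incidence`: per-arm named vectors of constant monthly
#'   incidences, one entry per type in the eight-type adverse-event profile.
#' @param costs List: `drug` (named monthly cost per arm, RM), `hhf_admission`,
#'   `cv_death`, `management` (monthly, single value or named per state),
#'   `ae` (named per type), `currency_year`.
#' @param utilities List: `state` (named utility per alive state),
#'   `hhf_decrement` (positive magnitude, applied for one cycle per event),
#'   `ae_decrement` (named per type).
#' @param econ List: `discount_cost`, `discount_outcome` (annual rates),
#'   `cycle_length_months`, `horizon` (`"lifetime"` or number of cycles),
#'   `cet` (RM/QALY), `half_cycle_correction`, `alive_tolerance`, `max_age`.
#' @param alternatives Optional named list of alternative blocks used by
#'   [run_scenario()]: `nyha` (full NYHA-state parameter block), `prices`
#'   (named drug-price tables), `survival_exponential` (exponential-survival
#'   alternative).
#' @return An object of class `hfcem_params`.
#' @export
parameter_set <- function(state_space, cohort, transitions, survival, hhf,
                          discontinuation, life_table, ae, costs, utilities,
                          econ = econ_settings(), alternatives = list()) {
  ps <- list(
    state_space = state_space, cohort = cohort, transitions = transitions,
    survival = survival, hhf = hhf, discontinuation = discontinuation,
    life_table = life_table, ae = ae, costs = costs, utilities = utilities,
    econ = econ, alternatives = alternatives
  )
  class(ps) <- "hfcem_params"
  ps
}

#' Economic settings with base-case defaults
#'
#' Defaults follow the base case: 3% annual discounting on costs and
#' outcomes, one-month cycles, a lifetime horizon (cohort followed to age
#' 100 or cohort extinction below `alive_tolerance`), half-cycle correction
#' on, and a cost-effectiveness threshold of RM 47,439 per QALY (one-time
#' 2021 GDP per capita).
#'
#' @param discount_cost,discount_outcome Annual discount rates.
#' @param cycle_length_months Cycle length in months.
#' @param horizon `"lifetime"` or an integer number of cycles.
#' @param cet Cost-effectiveness threshold, RM per QALY.
#' @param half_cycle_correction Apply the trapezoid correction to
#'   state-occupancy accruals?
#' @param alive_tolerance Stop a lifetime run once alive mass falls below this.
#' @param max_age Age (years) at which a lifetime run is truncated.
#' @return A list of settings.
#' @export
econ_settings <- function(discount_cost = 0.03, discount_outcome = 0.03,
                          cycle_length_months = 1, horizon = "lifetime",
                          cet = 47439, half_cycle_correction = TRUE,
                          alive_tolerance = 1e-6, max_age = 100) {
  list(discount_cost = discount_cost, discount_outcome = discount_outcome,
       cycle_length_months = cycle_length_months, horizon = horizon,
       cet = cet, half_cycle_correction = half_cycle_correction,
       alive_tolerance = alive_tolerance, max_age = max_age)
}

#' Parametric risk model on the log-hazard (or log-rate) scale
#'
#' Proportional-hazards form: the linear predictor
#' `eta(x) = intercept + treatment * b_trt + state effect` scales a Weibull
#' baseline, `S(t|x) = exp(-exp(eta(x)) * t^shape)` with time in months.
#' `shape = 1` (exponential) gives a constant hazard.
#'
#' @param distribution `"weibull"` or `"exponential"`.
#' @param shape Weibull shape (gamma); must be 1 for exponential.
#' @param intercept Log baseline scale.
#' @param treatment Additive log-hazard effect of being on treatment.
#' @param state Named vector of additive log-hazard effects per alive state
#'   (the reference state carries 0).
#' @return A list of class `hfcem_risk_model`.
#' @export
risk_model <- function(distribution = c("weibull", "exponential"), shape = 1,
                       intercept = 0, treatment = 0, state = numeric()) {
  distribution <- match.arg(distribution)
  if (distribution == "exponential") shape <- 1
  m <- list(distribution = distribution, shape = shape,
            coefficients = list(intercept = intercept, treatment = treatment,
                                state = state))
  class(m) <- "hfcem_risk_model"
  m
}

#' @export
print.hfcem_params <- function(x, ...) {
  cat("<hfcem_params> ", x$state_space$name, " states: ",
      paste(x$state_space$alive_states, collapse = ", "),
      "\n  cohort: age ", x$cohort$starting_age, ", ",
      round(100 * x$cohort$proportion_male), "% male\n",
      "  transition periods per arm: ",
      length(x$transitions$intervention), "\n",
      "  horizon: ", as.character(x$econ$horizon),
      ", CET RM ", format(x$econ$cet, big.mark = ","), "/QALY\n", sep = "")
  invisible(x)
}

# ---- validation ---------------------------------------------------------

#' Validate a parameter set
#'
#' Runs every structural invariant (row-stochastic matrices, probability
#' bounds, life-table coverage and CV-vs-all-cause ordering, cost
#' non-negativity, utility bounds, contiguous transition periods, ...) and
#' returns the violations as data: an empty data frame means the set is
#' valid. Violations never raise errors here, so the check is total.
#'
#' @param ps A `hfcem_params` object.
#' @return Data frame with columns `code`, `location`, `message`; zero rows
#'   if valid.
#' @export
validate_parameter_set <- function(ps) {
  v <- check_state_space(ps$state_space)
  states <- ps$state_space$alive_states

  # cohort
  init <- ps$cohort$initial_distribution
  if (length(init) != length(states) || any(init < 0))
    v <- add_violation(v, "cohort/init_distribution", "cohort",
                       "initial distribution must be non-negative over alive states")
  else if (abs(sum(init) - 1) > 1e-9)
    v <- add_violation(v, "cohort/init_sum", "cohort",
                       sprintf("initial distribution sums to %.12f, not 1", sum(init)))
  if (ps$cohort$proportion_male < 0 || ps$cohort$proportion_male > 1)
    v <- add_violation(v, "cohort/proportion_male", "cohort",
                       "proportion_male outside [0,1]")
  lt_ages <- range(ps$life_table$age)
  if (ps$cohort$starting_age < 18 || ps$cohort$starting_age >= lt_ages[2])
    v <- add_violation(v, "cohort/starting_age", "cohort",
                       "starting_age must be in [18, max life-table age)")

  # transitions
  for (arm in ARMS) {
    periods <- ps$transitions[[arm]]
    if (is.null(periods) || !length(periods)) {
      v <- add_violation(v, "transitions/missing_arm",
                         paste0("transitions.", arm), "arm has no matrices")
      next
    }
    expect_first <- 1
    for (i in seq_along(periods)) {
      p <- periods[[i]]
      loc <- sprintf("transitions.%s[%d]", arm, i)
      if (p$first != expect_first)
        v <- add_violation(v, "transitions/period_gap", loc,
                           sprintf("period starts at cycle %d, expected %d",
                                   p$first, expect_first))
      open <- is.na(p$last)
      if (open && i != length(periods))
        v <- add_violation(v, "transitions/open_not_last", loc,
                           "open-ended period must be last")
      if (!open) expect_first <- p$last + 1
      M <- p$matrix
      if (!is.matrix(M) || any(dim(M) != length(states))) {
        v <- add_violation(v, "transitions/shape", loc,
                           "matrix dimensions must match alive states")
        next
      }
      if (any(M < -1e-12 | M > 1 + 1e-12))
        v <- add_violation(v, "transitions/entry_bounds", loc,
                           "matrix entries outside [0,1]")
      bad <- which(abs(rowSums(M) - 1) > 1e-6)
      for (r in bad)
        v <- add_violation(v, "transitions/row_sum",
                           sprintf("%s row %d (%s)", loc, r, states[r]),
                           sprintf("row sums to %.8f", rowSums(M)[r]))
    }
    if (is.na(periods[[length(periods)]]$last) == FALSE)
      v <- add_violation(v, "transitions/last_not_open",
                         paste0("transitions.", arm),
                         "last period must be open-ended")
  }

  # risk models
  for (nm in c("survival.all_cause", "survival.cv", "discontinuation")) {
    m <- if (nm == "discontinuation") ps$discontinuation else
      ps$survival[[sub("survival\\.", "", nm)]]
    if (m$shape <= 0)
      v <- add_violation(v, "risk/shape", nm, "shape must be > 0")
    if (!m$distribution %in% c("weibull", "exponential"))
      v <- add_violation(v, "risk/distribution", nm, "unknown distribution")
    if (m$distribution == "exponential" && m$shape != 1)
      v <- add_violation(v, "risk/exponential_shape", nm,
                         "exponential model must have shape 1")
    missing_states <- setdiff(states, names(m$coefficients$state))
    if (length(missing_states))
      v <- add_violation(v, "risk/state_coefs", nm,
                         paste("missing state effects:",
                               paste(missing_states, collapse = ", ")))
  }
  if (length(setdiff(states, names(ps$hhf$coefficients$state))))
    v <- add_violation(v, "risk/state_coefs", "hhf", "missing state effects")

  # life table
  lt <- ps$life_table
  need <- c("age", "sex", "monthly_all_cause_q", "monthly_cv_q")
  if (!all(need %in% names(lt))) {
    v <- add_violation(v, "life_table/columns", "life_table",
                       "missing required columns")
  } else {
    if (any(lt$monthly_all_cause_q < 0 | lt$monthly_all_cause_q > 1) ||
        any(lt$monthly_cv_q < 0 | lt$monthly_cv_q > 1))
      v <- add_violation(v, "life_table/bounds", "life_table",
                         "probabilities outside [0,1]")
    bad <- which(lt$monthly_cv_q > lt$monthly_all_cause_q + 1e-15)
    for (r in bad)
      v <- add_violation(v, "life_table/cv_exceeds_all_cause",
                         sprintf("life_table age %d sex %s", lt$age[r], lt$sex[r]),
                         "CV death probability exceeds all-cause")
    for (sx in c("male", "female")) {
      ages <- sort(lt$age[lt$sex == sx])
      span <- seq(floor(ps$cohort$starting_age), ps$econ$max_age)
      if (!all(span %in% ages))
        v <- add_violation(v, "life_table/coverage", paste0("life_table ", sx),
                           "ages must cover starting_age through max_age")
    }
  }

  # adverse events
  for (arm in ARMS) {
    inc <- ps$ae$incidence[[arm]]
    miss <- setdiff(AE_TYPES, names(inc))
    if (length(miss))
      v <- add_violation(v, "ae/missing_type", paste0("ae.incidence.", arm),
                         paste("missing:", paste(miss, collapse = ", ")))
    bad <- names(inc)[inc < 0 | inc > 1]
    for (b in bad)
      v <- add_violation(v, "ae/bounds",
                         sprintf("ae.incidence.%s.%s", arm, b),
                         "incidence outside [0,1]")
  }

  # costs
  cs <- ps$costs
  if (any(cs$drug < 0) || length(setdiff(ARMS, names(cs$drug))))
    v <- add_violation(v, "costs/drug", "costs.drug",
                       "per-arm monthly drug costs must be present and >= 0")
  for (nm in c("hhf_admission", "cv_death")) {
    if (cs[[nm]] < 0)
      v <- add_violation(v, "costs/negative", paste0("costs.", nm),
                         "cost must be >= 0")
  }
  if (any(cs$management < 0))
    v <- add_violation(v, "costs/negative", "costs.management",
                       "cost must be >= 0")
  bad <- names(cs$ae)[cs$ae < 0]
  for (b in bad)
    v <- add_violation(v, "costs/negative_ae", paste0("costs.ae.", b),
                       "adverse-event cost must be >= 0")
  miss <- setdiff(AE_TYPES, names(cs$ae))
  if (length(miss))
    v <- add_violation(v, "costs/ae_missing", "costs.ae",
                       paste("missing:", paste(miss, collapse = ", ")))

  # utilities
  ut <- ps$utilities
  if (length(setdiff(states, names(ut$state))) ||
      any(ut$state < -1 | ut$state > 1))
    v <- add_violation(v, "utilities/state", "utilities.state",
                       "state utilities must cover alive states and lie in [-1,1]")
  if (ut$hhf_decrement < 0)
    v <- add_violation(v, "utilities/hhf_decrement", "utilities.hhf_decrement",
                       "decrement must be >= 0 (positive magnitude)")
  if (any(ut$ae_decrement < 0))
    v <- add_violation(v, "utilities/ae_decrement", "utilities.ae_decrement",
                       "decrements must be >= 0")

  # econ
  ec <- ps$econ
  if (ec$discount_cost < 0 || ec$discount_outcome < 0)
    v <- add_violation(v, "econ/discount", "econ", "discount rates must be >= 0")
  if (!identical(ec$horizon, "lifetime") &&
      (!is.numeric(ec$horizon) || ec$horizon < 1))
    v <- add_violation(v, "econ/horizon", "econ",
                       "horizon must be 'lifetime' or >= 1 cycle")
  if (ec$cet <= 0)
    v <- add_violation(v, "econ/cet", "econ", "CET must be > 0")

  rownames(v) <- NULL
  v
}

assert_valid <- function(ps) {
  v <- validate_parameter_set(ps)
  if (nrow(v)) {
    stop("invalid parameter set:\n",
         paste(sprintf("  [%s] %s: %s", v$code, v$location, v$message),
               collapse = "\n"), call. = FALSE)
  }
  invisible(ps)
}

# ---- price sets ---------------------------------------------------------

#' Swap in an alternative drug-price table
#'
#' Replaces only the per-arm monthly drug-acquisition costs (e.g. MoH
#' procurement prices instead of market prices); every other field is
#' untouched.
#'
#' @param ps A `hfcem_params` object.
#' @param prices Named numeric vector with entries `intervention` and
#'   `comparator` (RM per month).
#' @return A modified copy of `ps`.
#' @export
apply_price_set <- function(ps, prices) {
  miss <- setdiff(ARMS, names(prices))
  if (length(miss))
    stop("price table missing arm(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ps$costs$drug[ARMS] <- as.numeric(prices[ARMS])
  ps
}
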