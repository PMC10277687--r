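# Parametric risk equations -> per-cycle probabilities and expected counts.
#
# All models are proportional-hazards on the log scale with time measured in
# months since model entry (study time, not age): S(t|x) = exp(-exp(eta) *
# t^gamma), with eta = intercept + treatment * b_trt + state effect. Ageing
# enters only through the life-table floor on non-CV death.

#' Linear predictor of a risk model
#'
#' @param model A `hfcem_risk_model` (or the `hhf` coefficient list).
#' @param treatment 1 while on the add-on therapy, 0 otherwise.
#' @param state Alive-state label.
#' @return The linear predictor eta on the log-hazard (or log-rate) scale.
#' @keywords internal
linear_predictor <- function(model, treatment, state) {
  co <- model$coefficients
  if (!state %in% names(co$state))
    stop("unknown state '", state, "' in covariate profile", call. = FALSE)
  co$intercept + treatment * co$treatment + co$state[[state]]
}

#' Survival function of a parametric risk model
#'
#' `S(t|x) = exp(-exp(eta(x)) * t^shape)` with `t` in months; `S(0) = 1` and
#' the function is non-increasing in `t`.
#'
#' @inheritParams linear_predictor
#' @param t Time in months (>= 0); vectorised.
#' @return Survival probabilities in (0, 1].
#' @export
survival_at <- function(model, t, treatment = 0, state) {
  if (model$shape <= 0) stop("shape must be > 0", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  eta <- linear_predictor(model, treatment, state)
  exp(-exp(eta) * t^model$shape)
}

#' Conditional per-cycle death (or event) probability
#'
#' Probability of the event during cycle `cycle_index` (which spans months
#' `[cycle_index - 1, cycle_index)`) conditional on being event-free at its
#' start: `1 - S(t1)/S(t0)`. For exponential models this is constant across
#' cycles and equals `1 - exp(-h)` with `h` the monthly hazard.
#'
#' @inheritParams linear_predictor
#' @param cycle_index 1-based month index (vectorised).
#' @return Probabilities in [0, 1).
#' @export
cycle_death_prob <- function(model, cycle_index, treatment = 0, state) {
  if (any(cycle_index < 1)) stop("cycle_index must be >= 1", call. = FALSE)
  if (model$shape <= 0) stop("shape must be > 0", call. = FALSE)
  # 1 - S(t1)/S(t0) computed through the cumulative-hazard increment, which
  # is exact for the exponential case (time-constant, 1 - exp(-h)) and does
  # not underflow when S(t0) itself is vanishingly small
  eta <- linear_predictor(model, treatment, state)
  dH <- exp(eta) * (cycle_index^model$shape - (cycle_index - 1)^model$shape)
  1 - exp(-dH)
}

#' Per-cycle discontinuation probability
#'
#' Same survival-to-conditional-probability construction as
#' [cycle_death_prob()], applied to the time-to-discontinuation model. Only
#' meaningful for the on-treatment stratum of the intervention arm.
#'
#' @inheritParams cycle_death_prob
#' @export
discontinuation_prob <- function(model, cycle_index, treatment = 1, state) {
  cycle_death_prob(model, cycle_index, treatment, state)
}

#' Life-table lookup with sex-mix weighting
#'
#' @param lt Life-table data frame.
#' @param age Age in years (floored to completed years).
#' @param proportion_male Male fraction used to weight the sex-specific rows.
#' @return Named vector `c(all_cause = , cv = )` of monthly probabilities.
#' @keywords internal
life_table_q <- function(lt, age, proportion_male) {
  a <- floor(age)
  m <- lt[lt$age == a & lt$sex == "male", ]
  f <- lt[lt$age == a & lt$sex == "female", ]
  if (!nrow(m) || !nrow(f))
    stop("age ", a, " outside life table", call. = FALSE)
  w <- proportion_male
  c(all_cause = w * m$monthly_all_cause_q[1] + (1 - w) * f$monthly_all_cause_q[1],
    cv = w * m$monthly_cv_q[1] + (1 - w) * f$monthly_cv_q[1])
}

#' Per-cycle non-CV death probability with the general-population floor
#'
#' The model-based non-CV probability is the all-cause minus CV difference;
#' it is floored by the same difference taken from the age- and sex-specific
#' general-population life table (sex-mix weighted), whichever is highest.
#' This keeps modelled non-CV mortality at least as high as in the general
#' population.
#'
#' @param all_cause_p,cv_p Per-cycle model probabilities (cv_p <= all_cause_p).
#' @param lt Life-table data frame.
#' @param age Current cohort age in years.
#' @param proportion_male Male fraction of the cohort.
#' @return Probability in [0, 1].
#' @export
noncv_death_prob <- function(all_cause_p, cv_p, lt, age, proportion_male) {
  if (cv_p > all_cause_p + 1e-12)
    stop("cv_p exceeds all_cause_p", call. = FALSE)
  q <- life_table_q(lt, age, proportion_male)
  max(all_cause_p - cv_p, q[["all_cause"]] - q[["cv"]])
}

#' Expected heart-failure hospitalisations per cycle
#'
#' Rate of first and recurrent hHF admissions from the Poisson rate model:
#' `exp(eta(x))` per one-cycle exposure. Because multiple admissions per
#' patient are permitted, the value is an expected count and may exceed 1.
#'
#' @param model The `hhf` model (list with `coefficients`).
#' @inheritParams linear_predictor
#' @return Expected admissions per patient-cycle (> 0).
#' @export
hhf_expected_events <- function(model, treatment = 0, state) {
  exp(linear_predictor(model, treatment, state))
}

#' Constant per-cycle adverse-event probabilities
#'
#' @param ae The parameter set's `ae` block.
#' @param arm `"intervention"` or `"comparator"`.
#' @return Named per-type probability vector, constant over states and time.
#' @export
ae_cycle_probs <- function(ae, arm = c("intervention", "comparator")) {
  arm <- match.arg(arm)
  ae$incidence[[arm]]
}
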