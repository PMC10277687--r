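# Fixtures are built in code. base_ps() memoises the default synthetic
# parameter set; toy_ps() builds a minimal two-alive-state model whose
# expected behaviour can be computed by hand.

.fixture_env <- new.env(parent = emptyenv())

base_ps <- function() {
  if (is.null(.fixture_env$ps)) .fixture_env$ps <- generate_parameter_set()
  .fixture_env$ps
}

# ps with a short fixed horizon for analyses that re-run the engine many times
short_ps <- function(cycles = 120) {
  ps <- base_ps()
  ps$econ$horizon <- cycles
  ps
}

flat_life_table <- function(q_all = 0, q_cv = 0, min_age = 18,
                            max_age = 100) {
  ages <- min_age:max_age
  do.call(rbind, lapply(c("female", "male"), function(sx)
    data.frame(age = ages, sex = sx, monthly_all_cause_q = q_all,
               monthly_cv_q = q_cv, stringsAsFactors = FALSE)))
}

# Two alive states A (severe), B; single open-ended transition period; all
# hazards exponential (constant). Life-table floor negligible by default.
toy_ps <- function(matrix_int = diag(2), matrix_cmp = matrix_int,
                   init = c(A = 1, B = 0),
                   h_cv = 0, h_all_cause = h_cv, h_hhf = 0, h_disc = 0,
                   trt_cv = 0, trt_all_cause = 0, trt_hhf = 0,
                   utilities = c(A = 0.8, B = 0.8),
                   drug = c(intervention = 0, comparator = 0),
                   management = 0, hhf_admission = 0, cv_death = 0,
                   ae_scale = 0, hhf_decrement = 0,
                   discount = 0, horizon = 12, starting_age = 60,
                   life_table = flat_life_table(), hcc = TRUE) {
  states <- c("A", "B")
  log0 <- function(h) if (h > 0) log(h) else -745  # exp(-745) == 0
  mk_period <- function(M) {
    dimnames(M) <- list(states, states)
    list(list(first = 1L, last = NA_integer_, matrix = M))
  }
  zero_state <- stats::setNames(c(0, 0), states)
  ae_inc <- stats::setNames(rep(ae_scale, 8), hfcem:::AE_TYPES)
  parameter_set(
    state_space = custom_state_space(states),
    cohort = list(starting_age = starting_age, proportion_male = 0.5,
                  initial_distribution = stats::setNames(init, states)),
    transitions = list(intervention = mk_period(matrix_int),
                       comparator = mk_period(matrix_cmp)),
    survival = list(
      all_cause = risk_model("exponential", intercept = log0(h_all_cause),
                             treatment = trt_all_cause, state = zero_state),
      cv = risk_model("exponential", intercept = log0(h_cv),
                      treatment = trt_cv, state = zero_state)
    ),
    hhf = list(coefficients = list(intercept = log0(h_hhf),
                                   treatment = trt_hhf, state = zero_state)),
    discontinuation = risk_model("exponential", intercept = log0(h_disc),
                                 treatment = 0, state = zero_state),
    life_table = life_table,
    ae = list(incidence = list(intervention = ae_inc, comparator = ae_inc)),
    costs = list(drug = drug, hhf_admission = hhf_admission,
                 cv_death = cv_death,
                 management = stats::setNames(rep(management, 2), states),
                 ae = stats::setNames(rep(0, 8), hfcem:::AE_TYPES),
                 currency_year = 2021L),
    utilities = list(state = stats::setNames(utilities, states),
                     hhf_decrement = hhf_decrement,
                     ae_decrement = stats::setNames(rep(0, 8),
                                                    hfcem:::AE_TYPES)),
    econ = econ_settings(discount_cost = discount,
                         discount_outcome = discount,
                         horizon = horizon,
                         half_cycle_correction = hcc)
  )
}

expect_no_violations <- function(ps) {
  v <- validate_parameter_set(ps)
  expect_equal(nrow(v), 0, info = paste(utils::capture.output(print(v)),
                                        collapse = "\n"))
}
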