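neutral <- function(distribution = "weibull", shape = 1, intercept = 0,
                    treatment = 0) {
  risk_model(distribution, shape = shape, intercept = intercept,
             treatment = treatment, state = c(A = 0, B = 0))
}

# independent oracle: conditional cycle probability by numeric integration
# of the declared hazard h(t) = exp(eta) * gamma * t^(gamma - 1)
quad_cycle_prob <- function(eta, gamma, cycle) {
  H <- stats::integrate(function(t) exp(eta) * gamma * t^(gamma - 1),
                        cycle - 1, cycle, rel.tol = 1e-13)$value
  1 - exp(-H)
}

test_that("survival_at matches its closed form and is monotone", {
  m <- neutral(shape = 1, intercept = log(0.01))
  expect_equal(survival_at(m, 10, state = "A"), exp(-0.1), tolerance = 1e-12)
  expect_equal(survival_at(m, 0, state = "A"), 1)
  m2 <- neutral(shape = 2, intercept = log(1e-4))
  expect_lt(survival_at(m2, 20, state = "A"), survival_at(m2, 10, state = "A"))
  ts <- seq(0, 120, by = 0.5)
  s <- survival_at(m2, ts, state = "A")
  expect_true(all(diff(s) <= 0))
  expect_error(survival_at(neutral(shape = 1), -1, state = "A"), ">= 0")
})

test_that("exponential cycle probabilities are constant and exact", {
  m0 <- neutral("exponential", intercept = -745)
  expect_equal(cycle_death_prob(m0, 1:24, state = "A"), rep(0, 24))
  m <- neutral("exponential", intercept = log(0.02))
  p <- cycle_death_prob(m, 1:60, state = "A")
  expect_equal(p, rep(1 - exp(-0.02), 60), tolerance = 1e-15)
})

test_that("Weibull cycle probabilities agree with the quadrature oracle", {
  m <- neutral(shape = 2, intercept = log(1e-4))
  p10 <- cycle_death_prob(m, 10, state = "A")
  expect_equal(p10, quad_cycle_prob(log(1e-4), 2, 10), tolerance = 1e-10)

  set.seed(42)
  for (i in 1:100) {
    gamma <- stats::runif(1, 0.5, 3)
    eta <- stats::runif(1, -9, -3)
    trt <- stats::rnorm(1, 0, 0.3)
    st <- stats::rnorm(1, 0, 0.5)
    cyc <- sample(1:240, 1)
    m <- risk_model("weibull", shape = gamma, intercept = eta,
                    treatment = trt, state = c(A = st, B = 0))
    p <- cycle_death_prob(m, cyc, treatment = 1, state = "A")
    expect_equal(p, quad_cycle_prob(eta + trt + st, gamma, cyc),
                 tolerance = 1e-8)
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("Weibull with shape 1 reproduces the exponential model to 1e-12", {
  w <- neutral("weibull", shape = 1, intercept = log(0.015))
  e <- neutral("exponential", intercept = log(0.015))
  ts <- c(0, 0.5, 1, 7, 33.3, 120, 480)
  expect_equal(survival_at(w, ts, state = "A"),
               survival_at(e, ts, state = "A"), tolerance = 1e-12)
  expect_equal(cycle_death_prob(w, 1:120, state = "A"),
               cycle_death_prob(e, 1:120, state = "A"), tolerance = 1e-12)
})

test_that("non-CV death takes the max of model difference and life-table floor", {
  lt <- flat_life_table(q_all = 0.0015, q_cv = 0.0005) # floor 0.001
  expect_equal(noncv_death_prob(0.003, 0.001, lt, 60, 0.5), 0.002)
  expect_equal(noncv_death_prob(0.0015, 0.001, lt, 60, 0.5), 0.001)
  lt2 <- flat_life_table(q_all = 0.0008, q_cv = 0)
  expect_equal(noncv_death_prob(0.0008, 0, lt2, 60, 0.5), 0.0008)
  expect_error(noncv_death_prob(0.001, 0.002, lt, 60, 0.5), "exceeds")
  expect_error(noncv_death_prob(0.002, 0.001, lt, 150, 0.5), "life table")
})

test_that("life-table lookup weights sexes by the male fraction", {
  lt <- rbind(
    data.frame(age = 60, sex = "female", monthly_all_cause_q = 0.001,
               monthly_cv_q = 0.0004),
    data.frame(age = 60, sex = "male", monthly_all_cause_q = 0.002,
               monthly_cv_q = 0.0008)
  )
  q <- hfcem:::life_table_q(lt, 60.9, 0.76)
  expect_equal(q[["all_cause"]], 0.76 * 0.002 + 0.24 * 0.001)
  expect_equal(q[["cv"]], 0.76 * 0.0008 + 0.24 * 0.0004)
})

test_that("hHF expected events follow the Poisson log-linear form", {
  m0 <- list(coefficients = list(intercept = 0, treatment = 0,
                                 state = c(A = 0, B = 0)))
  expect_equal(hhf_expected_events(m0, 0, "A"), 1.0)
  m <- list(coefficients = list(intercept = log(0.02), treatment = log(0.7),
                                state = c(A = 0, B = 0)))
  expect_equal(hhf_expected_events(m, 0, "A"), 0.02, tolerance = 1e-15)
  expect_equal(hhf_expected_events(m, 1, "A"), 0.014, tolerance = 1e-15)
  # treated / untreated ratio is the rate ratio in every state
  ps <- base_ps()
  for (s in ps$state_space$alive_states) {
    expect_equal(hhf_expected_events(ps$hhf, 1, s) /
                   hhf_expected_events(ps$hhf, 0, s),
                 0.70, tolerance = 1e-12)
  }
})

test_that("discontinuation probabilities use the same survival construction", {
  m <- risk_model("exponential", intercept = log(0.01), treatment = 0,
                  state = c(A = 0, B = 0))
  p <- discontinuation_prob(m, 1:36, state = "A")
  expect_equal(p, rep(p[1], 36), tolerance = 0) # exactly time-constant
  expect_equal(p, rep(1 - exp(-0.01), 36), tolerance = 1e-12)
  m0 <- risk_model("exponential", intercept = -745, state = c(A = 0, B = 0))
  expect_equal(discontinuation_prob(m0, 5, state = "A"), 0)
  mw <- risk_model("weibull", shape = 1.4, intercept = log(0.008),
                   treatment = 0, state = c(A = 0, B = 0))
  p <- discontinuation_prob(mw, c(2, 20), state = "A")
  expect_false(p[1] == p[2]) # time-varying for shape != 1
  expect_equal(p[2], quad_cycle_prob(log(0.008), 1.4, 20), tolerance = 1e-10)
})

test_that("adverse-event probabilities are constant per arm and type", {
  ps <- base_ps()
  p_int <- ae_cycle_probs(ps$ae, "intervention")
  expect_length(p_int, 8)
  expect_true(all(p_int >= 0 & p_int <= 1))
  zero <- list(incidence = list(
    intervention = stats::setNames(rep(0, 8), names(p_int)),
    comparator = stats::setNames(rep(0, 8), names(p_int))))
  expect_true(all(ae_cycle_probs(zero, "comparator") == 0))

  # lifetime expected AE count equals sum over the trace of prob x exposure
  toy <- toy_ps(ae_scale = 0.002, horizon = 60)
  tr <- run_cohort(toy, "comparator") # no deaths: exposure = start mass
  alive_mass <- rowSums(tr$start_on + tr$start_off)
  expect_equal(unname(colSums(tr$ae)),
               rep(0.002 * sum(alive_mass), 8), tolerance = 1e-12)
})
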