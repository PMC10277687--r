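test_that("tornado rows are deterministic, order-invariant, and inert parameters rank last", {
  ps <- short_ps(60)
  spec <- data.frame(
    path = c("costs.drug.intervention", "costs.hhf_admission",
             "alternatives.prices.moh.intervention", # never read by the engine
             "costs.drug.intervention"),              # duplicate entry
    low = c(0.7 * ps$costs$drug[["intervention"]], 4200, 50,
            0.7 * ps$costs$drug[["intervention"]]),
    high = c(1.3 * ps$costs$drug[["intervention"]], 7800, 150,
             1.3 * ps$costs$drug[["intervention"]]),
    stringsAsFactors = FALSE
  )
  torn <- run_dsa(ps, spec)
  expect_equal(nrow(torn), 4)
  # the unused parameter has span 0 and sorts last
  expect_equal(torn$path[4], "alternatives.prices.moh.intervention")
  expect_equal(torn$span[4], 0)
  # duplicate entries give identical rows
  dup <- torn[torn$path == "costs.drug.intervention", ]
  expect_equal(dup[1, -1], dup[2, -1], ignore_attr = TRUE)
  # entry order does not change the spans
  torn2 <- run_dsa(ps, spec[c(3, 1, 4, 2), ])
  expect_equal(torn2$span, torn$span, tolerance = 1e-12)
  expect_equal(attr(torn, "base_icer"), run_ce(ps)$ce$icer_per_qaly)
})

test_that("the drug-cost ICER span equals the discounted-drug-mass oracle", {
  ps <- short_ps(120)
  p_int <- ps$costs$drug[["intervention"]]
  spec <- data.frame(path = "costs.drug.intervention",
                     low = 0.7 * p_int, high = 1.3 * p_int,
                     stringsAsFactors = FALSE)
  torn <- run_dsa(ps, spec)

  # oracle: only the intervention arm's drug component moves, linearly in
  # the price, through the discounted on-treatment membership
  tr <- run_cohort(ps, "intervention")
  dfc <- discount_factor(ps$econ$discount_cost, tr$cycle)
  m_on_disc <- sum(rowSums(tr$start_on + tr$end_on) / 2 * dfc)
  dQ <- run_ce(ps)$ce$delta_qaly
  expect_equal(torn$icer_high - torn$icer_low,
               0.6 * p_int * m_on_disc / dQ, tolerance = 1e-6)
})

test_that("zero-dispersion draws reproduce the base set; seeds make draws reproducible", {
  ps <- base_ps()
  degenerate <- psa_spec(list(
    list(path = "costs.hhf_admission", family = "gamma", se = 0),
    list(path = "utilities.hhf_decrement", family = "gamma", se = 0)
  ), iterations = 3, seed = 7)
  set.seed(1)
  expect_identical(sample_draw(ps, degenerate), ps)

  spec <- psa_default_spec(ps, iterations = 3, seed = 11)
  set.seed(5); d1 <- sample_draw(ps, spec)
  set.seed(5); d2 <- sample_draw(ps, spec)
  expect_identical(d1, d2)
  set.seed(6); d3 <- sample_draw(ps, spec)
  expect_false(identical(d1$costs$hhf_admission, d3$costs$hhf_admission))

  # Dirichlet-resampled rows stay stochastic
  set.seed(9)
  for (i in 1:50) {
    d <- sample_draw(ps, spec)
    for (p in d$transitions$intervention)
      expect_true(all(abs(rowSums(p$matrix) - 1) < 1e-9))
  }
})

test_that("a degenerate PSA equals the deterministic analysis exactly", {
  ps <- short_ps(60)
  spec <- psa_spec(list(
    list(path = "costs.drug.intervention", family = "gamma", se = 0)
  ), iterations = 5, seed = 3)
  psa <- run_psa(ps, spec)
  det <- run_ce(ps)$ce
  expect_equal(psa$draws$delta_cost, rep(det$delta_cost, 5), tolerance = 1e-12)
  expect_equal(psa$draws$delta_qaly, rep(det$delta_qaly, 5), tolerance = 1e-12)
  expect_equal(psa$redraws, 0)
  # CEAC is the step function of the deterministic ICER
  cv <- psa$ceac
  expect_true(all(cv$probability[cv$threshold < det$icer_per_qaly] == 0))
  expect_true(all(cv$probability[cv$threshold > det$icer_per_qaly] == 1))
})

test_that("PSA is reproducible from its seed and summarises the cloud coherently", {
  ps <- short_ps(60)
  spec <- psa_default_spec(ps, iterations = 25, seed = 42)
  r1 <- run_psa(ps, spec)
  r2 <- run_psa(ps, spec)
  expect_identical(r1$draws, r2$draws)
  expect_equal(sum(r1$quadrant_shares), 1, tolerance = 1e-12)
  expect_true(all(r1$ceac$probability >= 0 & r1$ceac$probability <= 1))
  # near-linear model: the mean cloud stays near the deterministic point
  det <- run_ce(ps)$ce
  se_c <- stats::sd(r1$draws$delta_cost) / sqrt(spec$iterations)
  se_q <- stats::sd(r1$draws$delta_qaly) / sqrt(spec$iterations)
  expect_lt(abs(mean(r1$draws$delta_cost) - det$delta_cost), 3 * se_c)
  expect_lt(abs(mean(r1$draws$delta_qaly) - det$delta_qaly), 3 * se_q)
})

test_that("the CEAC counts strictly positive net benefit", {
  draws <- data.frame(delta_cost = c(100, -50, 500, 200),
                      delta_qaly = c(0.01, 0.02, -0.001, 0.03))
  expect_equal(ceac(draws, 47439)$probability, 0.75)
  expect_equal(ceac(draws, 0)$probability, 0.25) # share with negative cost
  big <- ceac(draws[draws$delta_qaly > 0, ], c(1e5, 1e6, 1e7))$probability
  expect_equal(big[3], 1) # all effect-gaining draws accepted in the limit
  pos <- draws[draws$delta_qaly >= 0, ]
  curve <- ceac(pos, seq(0, 2e5, length.out = 40))$probability
  expect_true(all(diff(curve) >= 0)) # monotone when all dE >= 0
  expect_error(ceac(draws[0, ], 1000), "empty")
  # NMB exactly zero counts as not cost-effective
  tie <- data.frame(delta_cost = 100, delta_qaly = 0.01)
  expect_equal(ceac(tie, 10000)$probability, 0)
})

test_that("scenarios override only what they claim", {
  ps <- short_ps(120)
  expect_equal(run_scenario(ps, list())$ce, run_ce(ps)$ce)

  short <- run_scenario(ps, list(horizon_years = 1))
  expect_lt(abs(short$ce$delta_qaly), abs(run_ce(ps)$ce$delta_qaly))

  # with a never-binding life-table floor, starting age is inert
  toy <- toy_ps(h_cv = 0.004, h_all_cause = 0.006, h_hhf = 0.01,
                utilities = c(A = 0.7, B = 0.8),
                drug = c(intervention = 100, comparator = 50),
                hhf_admission = 1000, horizon = 120)
  r60 <- run_ce(toy)
  toy67 <- toy; toy67$cohort$starting_age <- 67
  r67 <- run_ce(toy67)
  expect_equal(r67$ce, r60$ce, tolerance = 1e-12)

  moh <- run_scenario(ps, list(prices = "moh"))
  expect_lt(moh$ce$delta_cost, run_ce(ps)$ce$delta_cost)
  expect_error(run_scenario(ps, list(prices = "nope")), "unknown price set")
  expect_error(run_scenario(ps, list(bogus = 1)), "unknown scenario")
})

test_that("the NYHA scenario swaps the whole state block", {
  ps <- short_ps(120)
  ny <- run_scenario(ps, list(state_space = "NYHA"))
  expect_equal(names(ny$intervention$discounted$ly),
               c("I", "II", "III_IV"))
  expect_true(is.finite(ny$ce$icer_per_qaly) || is.na(ny$ce$icer_per_qaly))
  bare <- ps; bare$alternatives$nyha <- NULL
  expect_error(run_scenario(bare, list(state_space = "NYHA")), "NYHA")
})

test_that("the exponential-survival scenario uses the alternative equations", {
  ps <- short_ps(120)
  ex <- run_scenario(ps, list(survival_distribution = "exponential"))
  base <- run_ce(ps)
  expect_false(isTRUE(all.equal(ex$ce$delta_qaly, base$ce$delta_qaly)))
  expect_equal(run_scenario(ps, list(survival_distribution = "weibull"))$ce,
               base$ce)
})
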