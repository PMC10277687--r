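test_that("discount factors follow the closed forms", {
  expect_equal(discount_factor(0.03, cycle_index = NULL, t_years = 0), 1.0)
  expect_equal(discount_factor(0.03, cycle_index = NULL, t_years = 1),
               1 / 1.03, tolerance = 1e-12)
  expect_equal(discount_factor(0.03, cycle_index = NULL, t_years = 0.5),
               1.03^-0.5, tolerance = 1e-12)
  # cycle 7 of monthly cycles is discounted at its midpoint, 6.5/12 years
  expect_equal(discount_factor(0.03, 7), 1.03^(-6.5 / 12), tolerance = 1e-12)
  expect_equal(discount_factor(0, 1:100), rep(1, 100))
  expect_error(discount_factor(-0.01, 1), ">= 0")
})

test_that("a flat alive year at utility 0.8 accrues LY 1 and QALY 0.8", {
  toy <- toy_ps(horizon = 12, utilities = c(A = 0.8, B = 0.8))
  res <- accrue(run_cohort(toy, "comparator"), toy$costs, toy$utilities,
                toy$econ)
  expect_equal(res$discounted$ly_total, 1.0, tolerance = 1e-12)
  expect_equal(res$discounted$qaly_total, 0.8, tolerance = 1e-12)
  expect_equal(res$undiscounted$ly_total, 1.0, tolerance = 1e-12)
  expect_equal(res$discounted$cost_total, 0)
})

test_that("immediate extinction leaves half a month of life", {
  toy <- toy_ps(h_cv = 1e6, horizon = 12)
  res <- accrue(run_cohort(toy, "comparator"), toy$costs, toy$utilities,
                toy$econ)
  expect_equal(res$discounted$ly_total, 1 / 24, tolerance = 1e-9)
})

test_that("accrual equals an independent cycle-by-cycle summation", {
  ps <- short_ps(180)
  for (arm in c("intervention", "comparator")) {
    tr <- run_cohort(ps, arm)
    res <- accrue(tr, ps$costs, ps$utilities, ps$econ)

    # brute-force reference written against the trace directly
    rc <- ps$econ$discount_cost; ro <- ps$econ$discount_outcome
    cost <- 0; qaly <- 0; ly <- 0
    for (k in seq_len(tr$n_cycles)) {
      dfc <- (1 + rc)^(-(k - 0.5) / 12)
      dfo <- (1 + ro)^(-(k - 0.5) / 12)
      mem <- (tr$start_on[k, ] + tr$start_off[k, ] +
                tr$end_on[k, ] + tr$end_off[k, ]) / 2
      m_on <- sum(tr$start_on[k, ] + tr$end_on[k, ]) / 2
      m_off <- sum(tr$start_off[k, ] + tr$end_off[k, ]) / 2
      cost <- cost + dfc * (m_on * ps$costs$drug[["intervention"]] +
                              m_off * ps$costs$drug[["comparator"]] +
                              sum(mem * ps$costs$management) +
                              tr$hhf[k] * ps$costs$hhf_admission +
                              tr$deaths_cv[k] * ps$costs$cv_death +
                              sum(tr$ae[k, ] * ps$costs$ae[colnames(tr$ae)]))
      ly <- ly + dfo * sum(mem) / 12
      qaly <- qaly + dfo * (sum(mem * ps$utilities$state) / 12 -
                              tr$hhf[k] * ps$utilities$hhf_decrement / 12 -
                              sum(tr$ae[k, ] *
                                    ps$utilities$ae_decrement[colnames(tr$ae)]) / 12)
    }
    expect_equal(res$discounted$cost_total, cost, tolerance = 1e-9)
    expect_equal(res$discounted$ly_total, ly, tolerance = 1e-9)
    expect_equal(res$discounted$qaly_total, qaly, tolerance = 1e-9)
  }
})

test_that("discounting never increases a component and vanishes at rate zero", {
  ps <- short_ps(240)
  res <- accrue(run_cohort(ps, "intervention"), ps$costs, ps$utilities,
                ps$econ)
  expect_true(all(res$discounted$cost <= res$undiscounted$cost + 1e-12))
  expect_lte(res$discounted$qaly_total, res$undiscounted$qaly_total)
  expect_lte(res$discounted$ly_total, res$undiscounted$ly_total)
  # decomposition identity as stored
  expect_equal(res$discounted$qaly_total,
               sum(res$discounted$qaly_state) - res$discounted$qaly_loss_hhf -
                 res$discounted$qaly_loss_ae, tolerance = 1e-12)
  expect_equal(res$discounted$cost_total, sum(res$discounted$cost),
               tolerance = 1e-12)

  ps0 <- ps
  ps0$econ$discount_cost <- 0
  ps0$econ$discount_outcome <- 0
  res0 <- accrue(run_cohort(ps0, "intervention"), ps0$costs, ps0$utilities,
                 ps0$econ)
  expect_equal(res0$discounted$cost_total, res0$undiscounted$cost_total,
               tolerance = 1e-12)
})

test_that("event rates per 100 patient-years are scale-invariant arithmetic", {
  expect_equal(event_rate_per_100py(50, 250), 20.0)
  expect_equal(event_rate_per_100py(0, 250), 0.0)
  expect_equal(event_rate_per_100py(2 * 50, 2 * 250), 20.0)
  expect_error(event_rate_per_100py(1, 0), "> 0")
})

fake_arm <- function(cost, qaly, ly) {
  structure(list(discounted = list(cost_total = cost, qaly_total = qaly,
                                   ly_total = ly)),
            class = "hfcem_arm_results")
}

test_that("incremental comparison reproduces printed-table arithmetic", {
  # per-arm totals as printed in the base-case table
  ce <- compare(fake_arm(25333, 3.64, 4.98), fake_arm(21675, 3.46, 4.84),
                econ_settings())
  expect_equal(ce$delta_cost, 3658)
  expect_equal(ce$delta_qaly, 0.18, tolerance = 1e-12)
  expect_equal(ce$delta_ly, 0.14, tolerance = 1e-10)
  expect_equal(ce$dominance, "trade-off")
  expect_true(ce$cost_effective)

  ce2 <- compare(fake_arm(1000, 0.05, 0.06), fake_arm(0, 0, 0),
                 econ_settings(cet = 47439))
  expect_equal(ce2$icer_per_qaly, 20000)
  expect_equal(ce2$nmb, 47439 * 0.05 - 1000, tolerance = 1e-9)
  expect_true(ce2$cost_effective)
})

test_that("dominance cases suppress the ratio", {
  dominant <- compare(fake_arm(-100, 0.1, 0.1), fake_arm(0, 0, 0),
                      econ_settings())
  expect_equal(dominant$dominance, "dominant")
  expect_true(is.na(dominant$icer_per_qaly))
  dominated <- compare(fake_arm(100, -0.1, -0.1), fake_arm(0, 0, 0),
                       econ_settings())
  expect_equal(dominated$dominance, "dominated")
  expect_true(is.na(dominated$icer_per_qaly))
})

test_that("comparing an arm with itself is null and undefined-ICER is data", {
  x <- fake_arm(1234.5, 2.2, 3.3)
  ce <- compare(x, x, econ_settings())
  expect_equal(ce$delta_cost, 0)
  expect_equal(ce$delta_qaly, 0)
  expect_true(is.na(ce$icer_per_qaly))
  expect_equal(ce$nmb, 0)

  odd <- compare(fake_arm(500, 1, 1), fake_arm(400, 1, 1), econ_settings())
  expect_true(is.na(odd$icer_per_qaly)) # dQALY below tolerance, no exception
})

test_that("raising the threshold never revokes cost-effectiveness (QALY-gaining case)", {
  int <- fake_arm(1000, 0.05, 0.05)
  cmp <- fake_arm(0, 0, 0)
  verdicts <- vapply(seq(1000, 100000, by = 1000), function(cet)
    compare(int, cmp, econ_settings(cet = cet))$cost_effective, logical(1))
  expect_true(all(diff(verdicts) >= 0))
})
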