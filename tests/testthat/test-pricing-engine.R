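worked_params <- function() {
  pricing_params(Pf = 100, cm = 20, cp = 1100, nt = 20, ns = 10, beta = 0.5)
}

random_params <- function() {
  Pf <- runif(1, 10, 500)
  cm <- runif(1, 0, Pf * 0.8)
  nt <- sample(2:500, 1)
  ns <- sample(0:(nt - 1), 1)
  pricing_params(Pf = Pf, cm = cm, cp = runif(1, 0, 5 * nt * Pf),
                 nt = nt, ns = ns, beta = runif(1, 0.01, 0.99))
}

test_that("no-show accounting is exact arithmetic", {
  expect_identical(no_show_count(100, 100), 0)
  expect_identical(no_show_count(100, 60), 40)
  expect_identical(no_show_count(20, 10), 10)
  expect_error(no_show_count(10, 11), "ns <= nt")
})

test_that("slot refill follows the reappointment model and its bound", {
  sf <- slot_fill(nn = 40, beta = 0.9)
  expect_equal(sf$nnr, 3.6, tolerance = 1e-12)
  expect_equal(sf$nsn, 32.4, tolerance = 1e-12)
  expect_lte(sf$nnr + sf$nsn, 40)

  expect_equal(slot_fill(40, 0)[c("nnr", "nsn")], list(nnr = 0, nsn = 0))
  expect_equal(slot_fill(40, 1)[c("nnr", "nsn")], list(nnr = 0, nsn = 40))

  # refill never exceeds vacancies for any beta in [0, 1]
  withr::with_seed(2, {
    for (i in 1:500) {
      nn <- runif(1, 0, 1000)
      b <- runif(1)
      sf <- slot_fill(nn, b)
      expect_lte(sf$nnr + sf$nsn, nn + 1e-12)
      expect_equal(sf$nnr + sf$nsn, nn * b, tolerance = 1e-9)
    }
  })
})

test_that("expected revenue is fee margin times demand minus fixed cost", {
  expect_equal(expected_revenue(pricing_params(100, 20, 3000, 100, 100, 0.5)),
               100 * 80 - 3000)
  expect_equal(expected_revenue(pricing_params(50, 10, 4000, 100, 100, 0.5)),
               0)  # break-even
  expect_equal(expected_revenue(pricing_params(50, 10, 700, 0, 0, 0.5)), -700)
})

test_that("revised revenue collapses correctly in the edge regimes", {
  # full fee as penalty: all refilled slots pay the standard margin
  p <- worked_params()
  with(p, expect_equal(revised_revenue(p, phi = Pf),
                       (ns + beta * (nt - ns)) * (Pf - cm) - cp,
                       tolerance = 1e-12))
  # no no-shows: revised equals expected revenue for any phi
  p2 <- pricing_params(100, 20, 1100, 20, 20, 0.5)
  for (phi in c(-50, 0, 60, 500)) {
    expect_equal(revised_revenue(p2, phi), expected_revenue(p2),
                 tolerance = 1e-12)
  }
  # plug-back of the worked example
  expect_equal(revised_revenue(worked_params(), 60), 0, tolerance = 1e-12)
})

test_that("the refill-form and per-term revenue formulas agree", {
  withr::with_seed(3, {
    for (i in 1:300) {
      p <- random_params()
      phi <- runif(1, -p$Pf, 3 * p$Pf)
      sf <- slot_fill(p$nt - p$ns, p$beta)
      alt <- (p$ns + sf$nsn) * (p$Pf - p$cm) + sf$nnr * (phi - p$cm) - p$cp
      expect_equal(revised_revenue(p, phi), alt, tolerance = 1e-12)
    }
  })
})

test_that("the zero-loss penalty fee solves the break-even condition", {
  pc <- penalty_cost(worked_params())
  expect_equal(pc$phi, 60, tolerance = 1e-12)
  expect_equal(pc$penalty_rate, 60, tolerance = 1e-12)
  expect_false(pc$below_material_cost)
  expect_false(pc$above_standard_fee)

  # numerator exactly zero: fee equals material cost
  expect_equal(penalty_cost(pricing_params(100, 20, 1000, 20, 10, 0.5))$phi,
               20, tolerance = 1e-12)

  expect_error(penalty_cost(pricing_params(100, 20, 1100, 20, 10, 1)),
               class = "undefined_penalty_error")
  expect_error(penalty_cost(pricing_params(100, 20, 1100, 20, 20, 0.5)),
               class = "undefined_penalty_error")

  # subsidy and super-fee regimes flagged, not clamped
  low <- penalty_cost(pricing_params(100, 20, 0, 20, 10, 0.5))
  expect_true(low$below_material_cost)
  expect_lt(low$phi, 20)
  high <- penalty_cost(pricing_params(100, 20, 2000, 20, 10, 0.5))
  expect_true(high$above_standard_fee)
  expect_gt(high$phi, 100)
})

test_that("phi rises with fixed cost; its ns-slope is set by Er's sign", {
  # Closed form: d(phi)/d(ns) = -Er / (beta * (1 - beta) * nn^2), so the
  # fee falls with attendance exactly when the full-attendance period is
  # profitable (Er > 0), and rises with attendance in a loss regime.
  withr::with_seed(4, {
    for (i in 1:200) {
      p <- random_params()
      if (p$ns >= p$nt - 1) next
      phi0 <- penalty_cost(p)$phi
      p_cp <- p; p_cp$cp <- p$cp + 100
      expect_gt(penalty_cost(p_cp)$phi, phi0)
      p_ns <- p; p_ns$ns <- p$ns + 1
      er <- expected_revenue(p)
      if (er > 1e-9) {
        expect_lt(penalty_cost(p_ns)$phi, phi0)
      } else if (er < -1e-9) {
        expect_gt(penalty_cost(p_ns)$phi, phi0)
      }
    }
  })
})

test_that("penalty rate and escalation behave as ratios of the fee", {
  expect_equal(penalty_rate(60, 100), 60)
  expect_equal(penalty_rate(0, 100), 0)
  expect_equal(penalty_rate(100, 100), 100)
  expect_error(penalty_rate(60, 0), "Pf")

  expect_equal(escalate_penalty(60, 1), 60)
  expect_equal(escalate_penalty(60, 2), 90)
  expect_equal(escalate_penalty(60, 3), 120)
  expect_equal(escalate_penalty(60, 7), 120)  # beyond sequence: last held
  expect_error(escalate_penalty(60, 0), "offence")
})

test_that("horizon simulation is seed-reproducible and guards degeneracy", {
  cfg <- horizon_config(horizon_days = 100)
  s1 <- simulate_horizon(c(RF = 0.975, AB = 0.950), cfg, seed = 5)
  s2 <- simulate_horizon(c(RF = 0.975, AB = 0.950), cfg, seed = 5)
  expect_identical(s1$daily, s2$daily)
  expect_identical(s1$average_rate, s2$average_rate)
  expect_identical(nrow(s1$daily), 200L)
  expect_equal(s1$average_rate[["RF"]],
               mean(s1$daily$rate[s1$daily$algorithm == "RF"], na.rm = TRUE))

  # no demand over the whole horizon: no contributing days
  expect_error(
    simulate_horizon(c(RF = 0.975),
                     horizon_config(horizon_days = 20, demand_mean = 1e-9),
                     seed = 5),
    "no contributing days")
  expect_error(simulate_horizon(c(0.9), cfg, seed = 5), "named")
  expect_error(simulate_horizon(c(RF = 1.0), cfg, seed = 5), "beta")
})
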