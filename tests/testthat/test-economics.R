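test_that("discount factors", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(10, 0.03), 0.7440939, tolerance = 1e-7)
  expect_equal(discount_factor(5, 0), 1)
  expect_true(all(diff(discount_factor(0:20, 0.03)) < 0))
})

test_that("undiscounted full-health QALYs equal the horizon length", {
  lt <- tibble::tibble(age = 55:65, sex = "total",
                       qx = c(rep(0, 10), 1))
  tr <- run_trace(default_parameters(),
                  strategy_spec("usual_care", NA, 55, horizon = 8),
                  incidence = 0, life = lt)
  acc <- accumulate(tr, default_parameters(), discount_rate = 0)
  expect_equal(acc$qaly, 8, tolerance = 1e-12)
  expect_equal(acc$cost, 8 * 26, tolerance = 1e-12) # usual care cost only
})

test_that("one false positive adds exactly its discounted work-up cost", {
  base <- tibble::tibble(
    cycle = 0:3, age = 55:58, healthy = 1, localized = 0, disseminated = 0,
    false_positive = 0, dead = 0, new_localized = 0, new_disseminated = 0,
    new_false_positive = 0, screens = 0)
  bumped <- base
  bumped$new_false_positive[3] <- 1 # event in cycle 2
  a0 <- accumulate(base, default_parameters())
  a1 <- accumulate(bumped, default_parameters())
  expect_equal(a1$cost - a0$cost, 2110 / 1.03^2, tolerance = 1e-12)
  expect_equal(a1$qaly, a0$qaly)
  # and one localized diagnosis adds its discounted surgical cost
  surg <- base
  surg$new_localized[2] <- 1
  expect_equal(accumulate(surg, default_parameters())$cost - a0$cost,
               13390 / 1.03, tolerance = 1e-12)
})

test_that("per-2-year costs are annualised on state occupancy", {
  tr <- tibble::tibble(
    cycle = 0:1, age = 55:56, healthy = 0, localized = 1, disseminated = 0,
    false_positive = 0, dead = 0, new_localized = 0, new_disseminated = 0,
    new_false_positive = 0, screens = 0)
  acc <- accumulate(tr, default_parameters(), discount_rate = 0)
  expect_equal(acc$cost, 2 * 19057 / 2, tolerance = 1e-12)
  expect_equal(acc$qaly, 2 * 0.825, tolerance = 1e-12)
})

test_that("accumulate reproduces the engine's accounting", {
  for (case in list(list(pop = "total", strat = strategy_spec("screening", 1)),
                    list(pop = "high_smoker",
                         strat = strategy_spec("screening", 2)),
                    list(pop = "high_smoker",
                         strat = strategy_spec("usual_care")))) {
    tr <- run_trace(default_parameters(), case$strat, incidence = case$pop)
    acc <- accumulate(tr, default_parameters())
    interval <- if (case$strat$arm == "screening") case$strat$interval else 1
    cea <- cea_screening(case$pop, interval)
    arm <- if (case$strat$arm == "screening") 2 else 1
    expect_equal(acc$cost, cea$arms$cost[arm], tolerance = 1e-9)
    expect_equal(acc$qaly, cea$arms$qaly[arm], tolerance = 1e-9)
  }
})

test_that("compare_arms computes increments, ICER and dominance", {
  res <- compare_arms(tibble::tibble(cost = 5493, qaly = 17.6911),
                      tibble::tibble(cost = 12408, qaly = 17.7314))
  expect_equal(res$incremental$delta_cost, 6915)
  expect_equal(res$incremental$delta_qaly, 0.0403, tolerance = 1e-9)
  expect_equal(res$incremental$icer, 6915 / 0.0403, tolerance = 1e-9)
  expect_equal(res$incremental$dominance, "trade-off")
  res2 <- compare_arms(tibble::tibble(cost = 100, qaly = 10),
                       tibble::tibble(cost = 90, qaly = 11))
  expect_equal(res2$incremental$dominance, "screening dominant")
  res3 <- compare_arms(tibble::tibble(cost = 100, qaly = 10),
                       tibble::tibble(cost = 120, qaly = 9))
  expect_equal(res3$incremental$dominance, "screening dominated")
  # no QALY difference: undefined ICER, flagged
  res4 <- compare_arms(tibble::tibble(cost = 100, qaly = 10),
                       tibble::tibble(cost = 120, qaly = 10))
  expect_true(is.na(res4$incremental$icer))
  expect_match(res4$incremental$dominance, "undefined")
})

test_that("worked biennial example", {
  res <- compare_arms(tibble::tibble(cost = 1000, qaly = 10),
                      tibble::tibble(cost = 1000 + 9066, qaly = 10.2))
  expect_equal(res$incremental$icer, 45330, tolerance = 1e-9)
})

test_that("discounting raises the ICER of screening", {
  # costs fall early (screens from cycle 0), QALY gains accrue late, so a
  # higher discount rate penalises the gains more than the costs
  icers <- vapply(c(0, 0.03, 0.06), function(r) {
    glance(cea_screening("total", 1, params = set_parameters(
      default_parameters(), discount_rate_annual = r)))$icer
  }, numeric(1))
  expect_true(all(diff(icers) > 0))
})

test_that("event summaries scale with cohort size", {
  res1 <- cea_screening("total", 1, cohort_n = 14218)
  res2 <- cea_screening("total", 1, cohort_n = 1)
  expect_equal(res1$events$screening$false_positives,
               14218 * res2$events$screening$false_positives, tolerance = 1e-9)
  expect_equal(res1$incremental$icer, res2$incremental$icer, tolerance = 1e-12)
})

test_that("ceac is the NMB exceedance fraction", {
  draws <- tibble::tibble(delta_cost = c(9066, 12000, -100),
                          delta_qaly = c(0.2, 0.18, 0.01))
  cc <- ceac(draws, thresholds = c(0, 50000, 70000))
  expect_equal(cc$prob_cost_effective, c(1 / 3, 2 / 3, 1))
  expect_error(ceac(draws[0, ]), "at least one draw")
  # monotone non-decreasing in the threshold when all delta_qaly > 0
  cc2 <- ceac(draws, thresholds = seq(0, 150000, 5000))
  expect_true(all(diff(cc2$prob_cost_effective) >= 0))
})
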