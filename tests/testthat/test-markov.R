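test_that("transition matrices are proper for any background mortality", {
  p <- default_parameters()
  for (strat in list(strategy_spec("usual_care"),
                     strategy_spec("screening", 1),
                     strategy_spec("screening", 2))) {
    for (age in c(55, 70, 90, 110)) {
      m <- transition_probs(age, "total", 0.00707, p, strat)
      expect_true(all(m >= 0))
      expect_equal(unname(rowSums(m)), rep(1, 5), tolerance = 1e-12)
      expect_equal(m["dead", "dead"], 1)
      expect_equal(sum(m["localized", c("healthy", "false_positive")]), 0)
      expect_equal(sum(m["disseminated", c("healthy", "false_positive")]), 0)
    }
  }
  # qx extremes via custom tables
  lt <- tibble::tibble(age = c(55L, 56L), sex = "total", qx = c(1, 1))
  m1 <- transition_probs(55, "total", 0.002, p, strategy_spec("screening", 1),
                        life = lt)
  expect_equal(unname(m1["healthy", ]), c(0, 0, 0, 0, 1))
})

test_that("healthy-row entries follow the documented event ordering", {
  p <- default_parameters()
  lt <- tibble::tibble(age = 69:71, sex = "total",
                       qx = c(0, 0, 1)) # isolate the diagnosis mechanics
  m <- transition_probs(69, "total", 0.0023, p, strategy_spec("screening", 1),
                        life = lt)
  plc <- (1 - exp(-0.0023)) * 1.13
  expect_equal(m["healthy", "localized"], plc * 0.702, tolerance = 1e-12)
  expect_equal(m["healthy", "disseminated"], plc * 0.298, tolerance = 1e-12)
  expect_equal(m["healthy", "false_positive"], (1 - plc) * 0.012,
               tolerance = 1e-12)
  expect_equal(m["healthy", "dead"], 0)
  # usual care: no false positives, usual stage split, no overdiagnosis
  mu <- transition_probs(69, "total", 0.0023, p, strategy_spec("usual_care"),
                         life = lt)
  expect_equal(mu["healthy", "false_positive"], 0)
  expect_equal(mu["healthy", "localized"] / (mu["healthy", "localized"] +
                 mu["healthy", "disseminated"]), 0.181, tolerance = 1e-12)
  expect_lt(mu["healthy", "localized"] + mu["healthy", "disseminated"],
            m["healthy", "localized"] + m["healthy", "disseminated"])
})

test_that("biennial constants and adaptation", {
  expect_equal(detected_interval_ratio(7.69, 2.76), 7.69 / 2.76)
  sp <- biennial_split(2.8)
  expect_equal(sp$screen_detected, 2.8 / 3.8, tolerance = 1e-12)
  expect_equal(sp$interval, 1 / 3.8, tolerance = 1e-12)
  expect_equal(sp$screen_detected + sp$interval, 1)
  ad <- biennial_adapt(default_parameters())
  expect_equal(ad$stage_frac_localized,
               2.8 / 3.8 * 0.702 + 1 / 3.8 * 0.181, tolerance = 1e-12)
  # effective multiplier bounded in [1, annual multiplier]
  expect_gte(ad$overdiagnosis_multiplier, 1)
  expect_lte(ad$overdiagnosis_multiplier, 1.13)
  # at the default detection-flow constants the lower bound binds
  expect_equal(ad$overdiagnosis_multiplier, 1)
  ad2 <- biennial_adapt(set_parameters(default_parameters(),
                                       biennial_detection_factor = 2))
  expect_equal(ad2$overdiagnosis_multiplier, 1.13)
})

test_that("trace conserves occupancy and dead is monotone", {
  for (strat in list(strategy_spec("usual_care"),
                     strategy_spec("screening", 1),
                     strategy_spec("screening", 2),
                     strategy_spec("screening", 2, start_age = 60,
                                   horizon = 10))) {
    tr <- run_trace(default_parameters(), strat, incidence = "high_smoker")
    occ <- tr$healthy + tr$localized + tr$disseminated +
      tr$false_positive + tr$dead
    expect_equal(occ, rep(1, nrow(tr)), tolerance = 1e-12)
    expect_true(all(diff(tr$dead) >= -1e-15))
    expect_true(all(as.matrix(tr[, health_states()]) >= -1e-15))
    expect_equal(tr$healthy[1], 1)
  }
})

test_that("three-cycle occupancy matches brute-force path enumeration", {
  p <- deterministic_parameters()
  lt <- default_life_table()
  rate <- 0.00707
  for (case in list(list(strat = strategy_spec("screening", 1),
                         od = 1.13, frac = 0.702, fps = c(0.012, 0.012, 0.012)),
                    list(strat = strategy_spec("screening", 2),
                         od = 1, frac = 2.8 / 3.8 * 0.702 + 1 / 3.8 * 0.181,
                         fps = c(0.012, 0, 0.012)),
                    list(strat = strategy_spec("usual_care"),
                         od = 1, frac = 0.181, fps = c(0, 0, 0)))) {
    mats <- lapply(1:3, function(t) {
      oracle_matrix(background_death_prob(lt, 54 + t, "total"), rate,
                    case$od, case$frac, case$fps[t],
                    p$hr_death_localized, p$hr_death_disseminated)
    })
    want <- oracle_occupancy(mats)
    tr <- run_trace(default_parameters(), case$strat, incidence = rate)
    got <- unlist(tr[tr$cycle == 3, health_states()])
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
  }
})

test_that("null intervention is exactly identical to usual care", {
  p0 <- set_parameters(default_parameters(),
                       stage_frac_localized_screen = 0.181,
                       stage_frac_disseminated_screen = 0.819,
                       hr_overdiagnosis = 1,
                       biennial_detection_factor = 2 / 1.13, # multiplier 1
                       fp_rate_per_screen = 0,
                       cost_screen_round = 0)
  for (interval in 1:2) {
    res <- cea_screening("total", interval, params = p0)
    expect_equal(res$incremental$delta_cost, 0, tolerance = 1e-12)
    expect_equal(res$incremental$delta_qaly, 0, tolerance = 1e-12)
    expect_true(is.na(res$incremental$icer))
  }
})

test_that("false positives are definitionally tied to screens and rate", {
  # with no mortality and no cancer, every screen of the healthy yields
  # fp_rate false positives
  lt <- tibble::tibble(age = rep(55:60, 3),
                       sex = rep(c("male", "female", "total"), each = 6),
                       qx = rep(c(0, 0, 0, 0, 0, 1), 3))
  tr <- run_trace(default_parameters(),
                  strategy_spec("screening", 1, 55, horizon = 4),
                  incidence = 0, life = lt)
  expect_equal(tr$new_false_positive, 0.012 * tr$healthy, tolerance = 1e-12)
  expect_equal(tr$screens, tr$healthy)
  # a false positive returns to healthy the next cycle
  expect_equal(tr$false_positive[-1], tr$new_false_positive[-nrow(tr)],
               tolerance = 1e-12)
})

test_that("cohort traces are occupancy-weighted averages (linearity)", {
  p <- default_parameters()
  strat <- strategy_spec("screening", 1, 55)
  entry <- tibble::tibble(age = c(55, 55, 60, 60, 60, 70),
                          sex = c("male", "male", "female", "female",
                                  "female", "male"))
  tr <- run_trace(p, strat, "total", entry = entry)
  parts <- list(
    run_trace(p, strat, "total", entry = list(age = 55, sex = "male")),
    run_trace(p, strat, "total", entry = list(age = 60, sex = "female")),
    run_trace(p, strat, "total", entry = list(age = 70, sex = "male"))
  )
  w <- c(2, 3, 1) / 6
  pad <- function(x, n) c(x, rep(utils::tail(x, 1) * 0, n - length(x)))
  n <- nrow(parts[[1]])
  dead_mix <- numeric(n)
  for (i in seq_along(parts)) {
    d <- parts[[i]]$dead
    k <- length(d)
    dead_mix <- dead_mix + w[i] * c(d, rep(1, n - k))
  }
  expect_equal(tr$dead, dead_mix, tolerance = 1e-12)
  occ <- tr$healthy + tr$localized + tr$disseminated + tr$false_positive +
    tr$dead
  expect_equal(occ, rep(1, n), tolerance = 1e-12)
  # younger-than-start subjects are bumped to the start age
  tr2 <- run_trace(p, strat, "total",
                   entry = tibble::tibble(age = c(40, 55), sex = "total"))
  tr3 <- run_trace(p, strat, "total", entry = list(age = 55, sex = "total"))
  expect_equal(tr2$dead, tr3$dead, tolerance = 1e-12)
})

test_that("strategy validation", {
  expect_error(strategy_spec("usual_care", interval = 1), "no screening interval")
  expect_error(strategy_spec("screening", interval = 3), "1 or 2")
  expect_error(strategy_spec("screening", 1, horizon = -2), "horizon")
  expect_error(strategy_spec("screening"), "1 or 2")
})
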