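test_that("default parameters satisfy their invariants", {
  p <- default_parameters()
  d <- deterministic_parameters(p)
  expect_equal(d$stage_frac_localized_usual + d$stage_frac_disseminated_usual, 1)
  expect_equal(d$stage_frac_localized_screen + d$stage_frac_disseminated_screen, 1)
  expect_equal(d$stage_frac_localized_usual, 0.181)
  expect_equal(d$stage_frac_localized_screen, 0.702)
  expect_equal(d$hr_overdiagnosis, 1.13)
  expect_equal(d$fp_rate_per_screen, 0.012)
  expect_equal(d$hr_death_localized, 2.68)
  expect_equal(d$hr_death_disseminated, 8.38)
  expect_equal(d$cost_screen_round, 189)
  expect_equal(d$cost_localized_surgical_oneoff, 13390)
  expect_equal(d$cost_false_positive, 2110)
  expect_equal(d$utility_localized, 0.825)
  expect_equal(d$utility_disseminated, 0.573)
  expect_equal(d$utility_false_positive, 1)
  expect_equal(d$discount_rate_annual, 0.03)
  expect_true(all(tidy(p)$low <= tidy(p)$deterministic))
  expect_true(all(tidy(p)$deterministic <= tidy(p)$high))
})

test_that("set_parameters replaces values and rejects unknown names", {
  p <- set_parameters(default_parameters(), fp_rate_per_screen = 0.233)
  expect_equal(deterministic_parameters(p)$fp_rate_per_screen, 0.233)
  expect_error(set_parameters(default_parameters(), nonsense = 1),
               "unknown parameter")
  # scalar replacement of a distributed parameter fixes it
  p2 <- set_parameters(default_parameters(), utility_disseminated = 0.5)
  expect_equal(draw_parameters(p2, 5, seed = 1)$utility_disseminated, rep(0.5, 5))
})

test_that("parameter draws are reproducible and respect supports", {
  p <- default_parameters()
  d1 <- draw_parameters(p, 500, seed = 7)
  d2 <- draw_parameters(p, 500, seed = 7)
  d3 <- draw_parameters(p, 500, seed = 8)
  expect_identical(d1, d2)
  expect_false(identical(d1, d3))
  expect_true(all(d1$utility_localized >= 0 & d1$utility_localized <= 1))
  expect_true(all(d1$cost_disseminated_per2y >= 0))
  # stage fraction pairs renormalized per draw
  expect_equal(d1$stage_frac_localized_usual + d1$stage_frac_disseminated_usual,
               rep(1, 500), tolerance = 1e-12)
  expect_equal(d1$stage_frac_localized_screen + d1$stage_frac_disseminated_screen,
               rep(1, 500), tolerance = 1e-12)
  # fixed parameters repeat their value
  expect_equal(unique(d1$hr_overdiagnosis), 1.13)
})

test_that("10,000 draws centre on the deterministic values", {
  d <- draw_parameters(default_parameters(), 10000, seed = 11)
  expect_equal(mean(d$utility_localized), 0.825, tolerance = 0.005)
  expect_equal(mean(d$utility_disseminated), 0.573, tolerance = 0.005)
  expect_equal(mean(d$stage_frac_localized_usual), 0.181, tolerance = 0.005)
  expect_equal(mean(d$cost_screen_round) / 189, 1, tolerance = 0.02)
})

test_that("parameter YAML round-trips exactly", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameter_config(default_parameters(), path)
  p <- read_parameter_config(path)
  expect_identical(tidy(p), tidy(default_parameters()))
})

test_that("bundled default configuration reproduces the defaults", {
  path <- system.file("extdata", "default_params.yaml", package = "asbscreen")
  expect_identical(tidy(read_parameter_config(path)),
                   tidy(default_parameters()))
})

test_that("unknown or missing configuration keys are errors", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameter_config(default_parameters(), path)
  txt <- readLines(path)
  writeLines(c(txt, "mystery_knob: 3"), path)
  expect_error(read_parameter_config(path), "unknown parameter key.*mystery_knob")
  writeLines(txt[!grepl("^hr_overdiagnosis", txt)], path)
  expect_error(read_parameter_config(path), "missing parameter key")
})

test_that("validation rejects incoherent parameter sets", {
  expect_error(set_parameters(default_parameters(), hr_death_localized = 0.5),
               ">= 1")
  expect_error(set_parameters(default_parameters(), utility_disseminated = 1.4),
               "in \\[0, 1\\]")
  expect_error(set_parameters(default_parameters(), cost_screen_round = -5),
               ">= 0")
  expect_error(set_parameters(default_parameters(),
                              stage_frac_localized_usual = 0.5),
               "sum to 1")
})
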