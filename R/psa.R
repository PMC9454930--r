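#' Probabilistic sensitivity analysis of a screening strategy
#'
#' Propagates parameter uncertainty through the cohort model: every
#' distributed input is sampled with [draw_parameters()] and both arms are
#' re-run per draw (the engine is vectorised across draws, so 10,000 draws
#' run the 5-state trace once with vector-valued parameters). The point
#' estimate is the deterministic run and does not depend on the seed.
#'
#' Draws in which screening gains no QALYs (`delta_qaly <= 0`) are retained
#' and flagged, not dropped; their per-draw ICER is reported as `NA` when the
#' QALY difference is numerically zero and is otherwise a signed ratio that
#' only the net-monetary-benefit view (see [ceac()]) orders correctly.
#'
#' @inheritParams cea_screening
#' @param n_draws Number of parameter draws.
#' @param seed Integer seed making the draw reproducible.
#' @return An `ascr_psa` object: `point` (the deterministic [cea_screening()]
#'   result), `draws` (per-draw arm costs/QALYs, increments, ICER and the
#'   non-positive-gain flag) and `summary` (mean, min-max and 2.5-97.5%
#'   percentile intervals per quantity).
#' @examples
#' psa <- run_psa("high_smoker", interval = 2, n_draws = 200, seed = 1)
#' glance(psa)
#' @export
run_psa <- function(population = "total", interval = 1, start_age = 55,
                    horizon = "lifetime", params = default_parameters(),
                    n_draws = 10000, seed = NULL,
                    life = default_life_table(), sex = "total",
                    use_age_bands = FALSE) {
  stopifnot(n_draws >= 1)
  point <- cea_screening(population, interval, start_age, horizon,
                         params = params, life = life, sex = sex,
                         use_age_bands = use_age_bands)
  draws <- draw_parameters(params, n_draws = n_draws, seed = seed)
  p <- as.list(draws)
  pop <- if (is.character(population)) population
  rate <- if (is.character(population)) incidence_rate(population)
  else population / 1000
  strat_u <- strategy_spec("usual_care", NA, start_age, horizon)
  strat_s <- strategy_spec("screening", interval, start_age, horizon)
  ru <- run_arm_engine(p, strat_u, life, rate, entry_age = start_age,
                       sex = sex, use_age_bands = use_age_bands,
                       population = pop)
  rs <- run_arm_engine(p, strat_s, life, rate, entry_age = start_age,
                       sex = sex, use_age_bands = use_age_bands,
                       population = pop)
  dC <- rs$cost - ru$cost
  dQ <- rs$qaly - ru$qaly
  d <- tibble(
    draw = seq_len(n_draws),
    cost_usual = ru$cost, qaly_usual = ru$qaly,
    cost_screen = rs$cost, qaly_screen = rs$qaly,
    delta_cost = dC, delta_qaly = dQ,
    icer = icer_value(dC, dQ),
    nonpositive_delta_qaly = dQ <= 0
  )
  pt <- c(cost_usual = point$arms$cost[1], qaly_usual = point$arms$qaly[1],
          cost_screen = point$arms$cost[2], qaly_screen = point$arms$qaly[2],
          delta_cost = point$incremental$delta_cost,
          delta_qaly = point$incremental$delta_qaly)
  smry <- purrr::imap(pt, function(v, nm) {
    x <- d[[nm]]
    tibble(quantity = nm, point = v, mean = mean(x),
           min = min(x), max = max(x),
           p2.5 = stats::quantile(x, 0.025, names = FALSE),
           p97.5 = stats::quantile(x, 0.975, names = FALSE))
  }) %>% list_rbind()
  structure(list(point = point, draws = d, summary = smry,
                 n_draws = n_draws, seed = seed,
                 population = point$population, strategy = point$strategy),
            class = "ascr_psa")
}

#' @export
print.ascr_psa <- function(x, ...) {
  cat(sprintf("<ascr_psa> %s, %d draws\n", x$population, x$n_draws))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 5)
  inc <- x$point$incremental
  cat(sprintf("  point ICER %s; %.1f%% of draws with delta QALY <= 0\n",
              if (is.na(inc$icer)) "undefined" else
                sprintf("%.0f EUR/QALY", inc$icer),
              100 * mean(x$draws$nonpositive_delta_qaly)))
  invisible(x)
}

#' Tidy a probabilistic sensitivity analysis
#'
#' @param x An `ascr_psa` object.
#' @param ... Unused.
#' @return The per-draw tibble (arm costs and QALYs, increments, ICER).
#' @exportS3Method generics::tidy
#' @export
tidy.ascr_psa <- function(x, ...) x$draws

#' One-row summary of a probabilistic sensitivity analysis
#'
#' @param x An `ascr_psa` object.
#' @param ... Unused.
#' @return A tibble with the point and mean increments, the point ICER and
#'   the share of draws with non-positive QALY gain.
#' @exportS3Method generics::glance
#' @export
glance.ascr_psa <- function(x, ...) {
  s <- x$summary
  get <- function(q, col) s[[col]][s$quantity == q]
  tibble(
    n_draws = x$n_draws,
    point_delta_cost = get("delta_cost", "point"),
    point_delta_qaly = get("delta_qaly", "point"),
    point_icer = x$point$incremental$icer,
    mean_delta_cost = get("delta_cost", "mean"),
    mean_delta_qaly = get("delta_qaly", "mean"),
    share_nonpositive_delta_qaly = mean(x$draws$nonpositive_delta_qaly)
  )
}

# complement partner for stage-fraction pairs that must sum to one
stage_fraction_partner <- c(
  stage_frac_localized_usual = "stage_frac_disseminated_usual",
  stage_frac_disseminated_usual = "stage_frac_localized_usual",
  stage_frac_localized_screen = "stage_frac_disseminated_screen",
  stage_frac_disseminated_screen = "stage_frac_localized_screen"
)

#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates the deterministic ICER with each distributed parameter set to
#' its low and then its high bound, all other inputs at base case. Stage
#' fractions are varied with their within-arm complement adjusted to keep the
#' pair summing to one. Parameters are returned sorted by the width of the
#' ICER swing.
#'
#' @inheritParams cea_screening
#' @return An `ascr_tornado` tibble: `parameter`, `low`, `high`,
#'   `icer_low`, `icer_high`, `span`, with the base-case ICER as attribute
#'   `icer_base`.
#' @examples
#' tornado_analysis(population = "high_smoker", interval = 2)
#' @export
tornado_analysis <- function(params = default_parameters(),
                             population = "high_smoker", interval = 2,
                             start_age = 55, horizon = "lifetime",
                             life = default_life_table()) {
  stopifnot(inherits(params, "ascr_params"))
  icer_base <- glance(cea_screening(population, interval, start_age, horizon,
                                    params = params, life = life))$icer
  td <- tidy(params)
  sweep <- td[td$family != "fixed" & td$high > td$low, ]
  eval_at <- function(nm, value) {
    repl <- stats::setNames(list(value), nm)
    partner <- stage_fraction_partner[nm]
    if (!is.na(partner)) repl[[unname(partner)]] <- 1 - value
    p2 <- do.call(set_parameters, c(list(params), repl))
    glance(cea_screening(population, interval, start_age, horizon,
                         params = p2, life = life))$icer
  }
  out <- if (nrow(sweep) == 0) {
    tibble(parameter = character(), low = numeric(), high = numeric(),
           icer_low = numeric(), icer_high = numeric(), span = numeric())
  } else {
    purrr::pmap(sweep[, c("parameter", "low", "high")],
                function(parameter, low, high) {
      tibble(parameter = parameter, low = low, high = high,
             icer_low = eval_at(parameter, low),
             icer_high = eval_at(parameter, high))
    }) %>%
      list_rbind() %>%
      mutate(span = abs(.data$icer_high - .data$icer_low)) %>%
      arrange(dplyr::desc(.data$span))
  }
  structure(out, class = c("ascr_tornado", class(out)),
            icer_base = icer_base, population = population,
            interval = interval, start_age = start_age)
}

#' Deterministic scenario grid
#'
#' Runs the deterministic cost-effectiveness analysis over every combination
#' of eligibility stratum, programme start age and screening interval, the
#' policy-facing summary of the model: which populations and designs fall
#' under a given willingness-to-pay threshold.
#'
#' @param populations `population` labels from [subgroup_incidence()].
#' @param start_ages Programme start ages.
#' @param intervals Screening intervals in years.
#' @inheritParams cea_screening
#' @return A tibble with one row per scenario: `population`, `start_age`,
#'   `interval`, `delta_cost`, `delta_qaly`, `icer`, `dominance`.
#' @examples
#' scenario_grid(populations = c("total", "high_smoker"), start_ages = 55)
#' @export
scenario_grid <- function(populations = subgroup_incidence()$population,
                          start_ages = c(50, 55, 60), intervals = c(1, 2),
                          params = default_parameters(),
                          life = default_life_table(),
                          horizon = "lifetime") {
  grid <- tidyr::expand_grid(population = populations, start_age = start_ages,
                             interval = intervals)
  purrr::pmap(grid, function(population, start_age, interval) {
    g <- glance(cea_screening(population, interval, start_age, horizon,
                              params = params, life = life))
    tibble(population = population, start_age = start_age,
           interval = interval) %>% bind_cols(g)
  }) %>% list_rbind()
}
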