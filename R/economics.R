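#' Discount factor
#'
#' Present-value factor `1 / (1 + r)^t` applied to costs and QALYs alike.
#'
#' @param t Years since model entry (cycle index, 0-based).
#' @param rate Annual discount rate.
#' @return Discount factor(s).
#' @examples
#' discount_factor(10, 0.03) # 0.74409
#' @export
discount_factor <- function(t, rate = 0.03) (1 + rate)^(-t)

#' Accumulate discounted costs and QALYs along a trace
#'
#' For each cycle `t` (start-of-cycle occupancy, discounted by
#' `1/(1+r)^t`): costs are the usual-care annual cost on healthy occupants
#' (both arms), the screening-round cost per screen performed, the
#' false-positive work-up cost per new false positive, the one-off surgical
#' cost per new localized diagnosis, and the per-2-year localized
#' post-surgical and disseminated care costs annualised (divided by 2) on
#' state occupancy. QALYs are occupancy times state utility. No half-cycle
#' correction is applied; the cycle of state entry accrues the entered
#' state's cost and utility in full (the trace's occupancy rows realise
#' this bookkeeping).
#'
#' @param trace A trace from [run_trace()].
#' @param params Parameters (`ascr_params` or one-row tibble).
#' @param discount_rate Annual discount rate; defaults to the parameter set's.
#' @return A one-row tibble: `cost` and `qaly` per person (discounted).
#' @export
accumulate <- function(trace, params, discount_rate = NULL) {
  p <- as_param_row(params)
  r <- discount_rate %||% p$discount_rate_annual
  v <- discount_factor(trace$cycle, r)
  cost <- sum(v * (p$cost_usual_annual * trace$healthy +
                     p$cost_screen_round * trace$screens +
                     p$cost_false_positive * trace$new_false_positive +
                     p$cost_localized_surgical_oneoff * trace$new_localized +
                     p$cost_localized_postsurgical_per2y / 2 * trace$localized +
                     p$cost_disseminated_per2y / 2 * trace$disseminated))
  qaly <- sum(v * (p$utility_healthy * trace$healthy +
                     p$utility_localized * trace$localized +
                     p$utility_disseminated * trace$disseminated +
                     p$utility_false_positive * trace$false_positive))
  if (cost < 0 || qaly < 0) abort("negative accumulated cost or QALYs")
  tibble(cost = cost, qaly = qaly)
}

icer_value <- function(dC, dQ, tol = 1e-9) {
  ifelse(abs(dQ) < tol, NA_real_, dC / dQ)
}

#' Compare two strategy accumulations
#'
#' @param usual,screen One-row tibbles with `cost` and `qaly` (per person,
#'   discounted), computed under identical parameter values and horizons;
#'   optionally with event columns (`false_positives`, `localized`,
#'   `disseminated`, `screens`).
#' @param cohort_n Cohort size used to scale event summaries.
#' @return An `ascr_cea` object; see [cea_screening()].
#' @examples
#' compare_arms(tibble::tibble(cost = 5493, qaly = 17.6911),
#'              tibble::tibble(cost = 12408, qaly = 17.7314))
#' @export
compare_arms <- function(usual, screen, cohort_n = 14218) {
  if (nrow(usual) != 1 || nrow(screen) != 1) {
    abort("compare_arms expects one accumulation row per arm")
  }
  dC <- screen$cost - usual$cost
  dQ <- screen$qaly - usual$qaly
  icer <- icer_value(dC, dQ)
  dominance <- dplyr::case_when(
    is.na(icer) ~ "undefined (no QALY difference)",
    dC <= 0 & dQ > 0 ~ "screening dominant",
    dC > 0 & dQ < 0 ~ "screening dominated",
    TRUE ~ "trade-off"
  )
  ev <- function(tb) {
    cols <- intersect(c("false_positives", "localized", "disseminated",
                        "screens"), names(tb))
    if (!length(cols)) return(NULL)
    tb[, cols] * cohort_n
  }
  structure(list(
    arms = bind_rows(
      usual %>% mutate(arm = "usual_care", .before = 1),
      screen %>% mutate(arm = "screening", .before = 1)),
    incremental = tibble(delta_cost = dC, delta_qaly = dQ, icer = icer,
                         dominance = dominance),
    events = list(usual = ev(usual), screening = ev(screen)),
    cohort_n = cohort_n
  ), class = "ascr_cea")
}

#' Deterministic cost-effectiveness analysis of a screening strategy
#'
#' Runs the usual-care and screening arms at the deterministic parameter
#' values for one stratum and start age, and returns per-person discounted
#' costs and QALYs, their increments, the ICER and event summaries scaled to
#' the cohort size. The whole cohort enters the model at the start age (the
#' programme's first screen); subjects are followed to age 110 under a
#' lifetime horizon.
#'
#' @param population Stratum label from [subgroup_incidence()], or a numeric
#'   incidence per 1000 person-years.
#' @param interval Screening interval in years (1 or 2).
#' @param start_age Programme start age (50, 55 or 60 in the scenario grid).
#' @param horizon `"lifetime"` or a number of cycles.
#' @param params Parameters.
#' @param life Life table.
#' @param sex Life-table column (`"total"` reproduces the published
#'   programme; `"male"`/`"female"` or a weighted pair via `sex_weights`).
#' @param sex_weights Optional named weights (e.g.
#'   `c(male = 0.948, female = 0.052)`) blending sex-specific runs at the
#'   individual level.
#' @param cohort_n Cohort size for event scaling.
#' @param use_age_bands Use age-band incidence rates over the trace rather
#'   than the stratum's all-ages rate.
#' @return An `ascr_cea` object with `arms`, `incremental`, `events`.
#' @examples
#' cea_screening("total", interval = 1)
#' @export
cea_screening <- function(population = "total", interval = 1, start_age = 55,
                          horizon = "lifetime", params = default_parameters(),
                          life = default_life_table(), sex = "total",
                          sex_weights = NULL, cohort_n = 14218,
                          use_age_bands = FALSE) {
  p <- as_param_row(params)
  pop <- if (is.character(population)) population
  rate <- if (is.character(population)) incidence_rate(population)
  else population / 1000
  strat_u <- strategy_spec("usual_care", NA, start_age, horizon)
  strat_s <- strategy_spec("screening", interval, start_age, horizon)
  run1 <- function(strategy) {
    if (is.null(sex_weights)) {
      run_arm_engine(p, strategy, life, rate, entry_age = start_age, sex = sex,
                     use_age_bands = use_age_bands, population = pop)
    } else {
      parts <- purrr::imap(as.list(sex_weights), function(w, sx) {
        w * run_arm_engine(p, strategy, life, rate, entry_age = start_age,
                           sex = sx, use_age_bands = use_age_bands,
                           population = pop)
      })
      Reduce(`+`, parts) / sum(unlist(sex_weights))
    }
  }
  res <- compare_arms(run1(strat_u), run1(strat_s), cohort_n = cohort_n)
  res$population <- if (is.character(population)) population else
    sprintf("rate %.2f per 1000 py", population)
  res$strategy <- strat_s
  res
}

#' @export
print.ascr_cea <- function(x, ...) {
  cat("<ascr_cea>", x$population %||% "", "\n")
  print(as.data.frame(x$arms), row.names = FALSE)
  inc <- x$incremental
  cat(sprintf("  delta cost %.0f EUR, delta QALY %.4f, ICER %s (%s)\n",
              inc$delta_cost, inc$delta_qaly,
              if (is.na(inc$icer)) "undefined" else sprintf("%.0f EUR/QALY", inc$icer),
              inc$dominance))
  invisible(x)
}

#' Tidy a cost-effectiveness result
#'
#' @param x An `ascr_cea` object.
#' @param ... Unused.
#' @return Per-arm tibble of discounted cost and QALYs.
#' @exportS3Method generics::tidy
#' @export
tidy.ascr_cea <- function(x, ...) x$arms

#' One-row summary of a cost-effectiveness result
#'
#' @param x An `ascr_cea` object.
#' @param ... Unused.
#' @return A tibble with `delta_cost`, `delta_qaly`, `icer`, `dominance`.
#' @exportS3Method generics::glance
#' @export
glance.ascr_cea <- function(x, ...) x$incremental

#' Cost-effectiveness acceptability curve
#'
#' Fraction of probabilistic draws for which screening is cost-effective —
#' net monetary benefit `lambda * dQ - dC > 0` — at each willingness-to-pay
#' threshold.
#'
#' @param draws A tibble with columns `delta_cost` and `delta_qaly` (e.g.
#'   `tidy(run_psa(...))`), or an `ascr_psa` object.
#' @param thresholds Willingness-to-pay grid (euro per QALY).
#' @return A tibble (`threshold`, `prob_cost_effective`), classed
#'   `ascr_ceac` for [autoplot()].
#' @examples
#' ceac(tibble::tibble(delta_cost = c(9066, 12000),
#'                     delta_qaly = c(0.2, 0.18)),
#'      thresholds = c(0, 50000))
#' @export
ceac <- function(draws, thresholds = seq(0, 150000, by = 5000)) {
  if (inherits(draws, "ascr_psa")) draws <- draws$draws
  if (!nrow(draws)) abort("ceac requires at least one draw")
  out <- tibble(
    threshold = thresholds,
    prob_cost_effective = vapply(
      thresholds,
      function(l) mean(l * draws$delta_qaly - draws$delta_cost > 0),
      numeric(1))
  )
  structure(out, class = c("ascr_ceac", class(out)))
}
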