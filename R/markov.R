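#' Health states of the screening model
#'
#' The model distinguishes five states: in good health, localized lung cancer
#' (stage I-II), disseminated lung cancer (stage III-IV), false-positive
#' screening finding, and dead. Dead is absorbing; the cancer states exit
#' only to death (cure, progression and death are pooled in a single
#' stage-specific exit hazard); a false positive returns to good health after
#' one cycle unless background mortality intervenes.
#'
#' @return Character vector of the five state names, in trace order.
#' @export
health_states <- function() {
  c("healthy", "localized", "disseminated", "false_positive", "dead")
}

#' Define a screening strategy
#'
#' @param arm `"usual_care"` or `"screening"`.
#' @param interval Years between screens (1 or 2); must be `NA` for usual
#'   care.
#' @param start_age Age at model entry / first screen (years).
#' @param horizon `"lifetime"` (run to age 110) or a number of 1-year cycles
#'   (e.g. `10`).
#' @return A `strategy_spec` list.
#' @examples
#' strategy_spec("screening", interval = 2, start_age = 55)
#' @export
strategy_spec <- function(arm = c("usual_care", "screening"), interval = NA,
                          start_age = 55, horizon = "lifetime") {
  arm <- match.arg(arm)
  if (arm == "usual_care" && !is.na(interval)) {
    abort("usual care has no screening interval")
  }
  if (arm == "screening" && !interval %in% c(1, 2)) {
    abort("screening interval must be 1 or 2 years")
  }
  if (!(identical(horizon, "lifetime") || (is.numeric(horizon) && horizon >= 1))) {
    abort("horizon must be \"lifetime\" or a positive number of cycles")
  }
  structure(list(arm = arm, interval = interval, start_age = start_age,
                 horizon = horizon),
            class = "strategy_spec")
}

#' @export
print.strategy_spec <- function(x, ...) {
  cat(sprintf("<strategy> %s%s, start age %d, horizon %s\n", x$arm,
              if (x$arm == "screening") sprintf(" every %d y", x$interval) else "",
              x$start_age,
              if (identical(x$horizon, "lifetime")) "lifetime" else
                paste(x$horizon, "cycles")))
  invisible(x)
}

#' Screen-detected / interval-cancer split for biennial screening
#'
#' With two years between screens some cancers surface clinically between
#' scans ("interval cancers"). The screen-detected : interval ratio observed
#' with a 2-year-like interval is `r` (7.69 vs 2.76 cancers per 1000 scans,
#' i.e. about 2.8:1), so a fraction `r/(r+1)` of diagnoses carries the
#' screen-detected stage distribution and `1/(r+1)` the usual-care one.
#'
#' @param r Detected-to-interval ratio (> 0).
#' @return A named list `screen_detected`, `interval` (fractions summing
#'   to 1).
#' @examples
#' biennial_split(2.8) # 0.7368 / 0.2632
#' @export
biennial_split <- function(r = 2.8) {
  stopifnot(r > 0)
  list(screen_detected = r / (r + 1), interval = 1 / (r + 1))
}

#' Detected-to-interval ratio from per-1000-scan yields
#'
#' @param detected_per_1000 Screen-detected cancers per 1000 scans.
#' @param interval_per_1000 Interval cancers per 1000 scans.
#' @return The ratio.
#' @examples
#' detected_interval_ratio(7.69, 2.76) # ~2.8
#' @export
detected_interval_ratio <- function(detected_per_1000 = 7.69,
                                    interval_per_1000 = 2.76) {
  detected_per_1000 / interval_per_1000
}

#' Biennial adaptation of the screening arm
#'
#' Derives the effective per-diagnosis stage split and the effective
#' overdiagnosis multiplier of a biennial programme from three constants: the
#' screen-detected : interval ratio `r` (2.8), the per-screen detection-yield
#' factor (1.5: a biennial screen detects 1.5 times as many cancers as an
#' annual one), and the annual-arm overdiagnosis hazard ratio (1.13).
#'
#' Screen-detected cancers (fraction `r/(r+1)`) carry the screening stage
#' fractions; interval cancers (fraction `1/(r+1)`) carry the usual-care
#' stage fractions and no overdiagnosis. The biennial arm's total incidence
#' multiplier is the annual multiplier scaled by the biennial/annual
#' detection-flow ratio (`detection_factor / 2`, i.e. 1.5 times the per-screen
#' yield at half the screening frequency = 0.75), bounded below by 1 (a
#' lifetime horizon cannot diagnose fewer cancers than arise) and above by
#' the annual arm's multiplier: `min(max(1, hr_od * factor/2), hr_od)`. At
#' the default values this floor binds and biennial screening carries no net
#' overdiagnosis.
#'
#' @param params An `ascr_params` object or one-row parameter tibble.
#' @param two_year_incidence Optional 2-year diagnosis probability to split
#'   (e.g. `1 - (1 - p1)^2`); if supplied, absolute compartment
#'   probabilities are returned as well.
#' @return A list: `fractions` (screen-detected / interval shares),
#'   `stage_frac_localized` (effective localized share per diagnosis),
#'   `overdiagnosis_multiplier`, and, when `two_year_incidence` is given,
#'   `p_screen_detected` / `p_interval`.
#' @examples
#' biennial_adapt(default_parameters())
#' @export
biennial_adapt <- function(params = default_parameters(),
                           two_year_incidence = NULL) {
  p <- as_param_row(params)
  sp <- biennial_split(p$detected_to_interval_ratio)
  frac_loc <- sp$screen_detected * p$stage_frac_localized_screen +
    sp$interval * p$stage_frac_localized_usual
  od <- pmin(pmax(1, p$hr_overdiagnosis * p$biennial_detection_factor / 2),
             p$hr_overdiagnosis)
  out <- list(fractions = sp, stage_frac_localized = frac_loc,
              overdiagnosis_multiplier = od)
  if (!is.null(two_year_incidence)) {
    out$p_screen_detected <- two_year_incidence * sp$screen_detected
    out$p_interval <- two_year_incidence * sp$interval
  }
  out
}

# normalize ascr_params / one-row tibble / named list to a named list of
# deterministic values (or vectors, for PSA rows)
as_param_row <- function(params) {
  if (inherits(params, "ascr_params")) {
    return(as.list(deterministic_parameters(params)))
  }
  if (is.data.frame(params)) return(as.list(params))
  if (is.list(params)) return(params)
  abort("params must be an ascr_params object or a parameter tibble")
}

# per-arm diagnosis dynamics: overdiagnosis multiplier and localized share
arm_dynamics <- function(p, strategy) {
  if (strategy$arm == "usual_care") {
    list(od = rep(1, length(p$hr_overdiagnosis)),
         frac_loc = p$stage_frac_localized_usual /
           (p$stage_frac_localized_usual + p$stage_frac_disseminated_usual))
  } else if (strategy$interval == 1) {
    list(od = p$hr_overdiagnosis,
         frac_loc = p$stage_frac_localized_screen /
           (p$stage_frac_localized_screen + p$stage_frac_disseminated_screen))
  } else {
    ad <- biennial_adapt(p)
    list(od = ad$overdiagnosis_multiplier, frac_loc = ad$stage_frac_localized)
  }
}

horizon_cycles <- function(strategy, entry_age, max_age = 110) {
  if (identical(strategy$horizon, "lifetime")) max_age - entry_age + 1
  else as.integer(strategy$horizon)
}

#' One-cycle transition probability matrix
#'
#' Builds the 5x5 transition matrix for one cycle at a given age. From the
#' healthy state, events within a cycle are ordered and mutually exclusive:
#' background death first (probability `qx`), then lung-cancer diagnosis
#' among survivors (`(1 - exp(-rate)) * od`, split into localized /
#' disseminated by the arm's stage fractions), then a false-positive screen
#' among surviving undiagnosed subjects (`fp_rate`, in screening cycles
#' only). Cancer states exit to death with [lc_death_prob()] at the
#' stage-specific hazard ratio; a false positive returns to health unless
#' dying at `qx`; death is absorbing. Rows sum to one for any `qx` in
#' `[0, 1]`.
#'
#' @param age Integer age during the cycle.
#' @param sex Life-table column.
#' @param incidence_rate Lung-cancer incidence per person-year.
#' @param params Parameters (`ascr_params` or one-row tibble).
#' @param strategy A [strategy_spec()].
#' @param life Life table.
#' @param cycle Cycle index (0-based) used to decide whether this is a
#'   screening cycle under a 2-year interval.
#' @return A 5x5 matrix with `dimnames` [health_states()].
#' @examples
#' transition_probs(70, "total", 0.00707, default_parameters(),
#'                  strategy_spec("screening", 1))
#' @export
transition_probs <- function(age, sex = "total", incidence_rate, params,
                             strategy, life = default_life_table(),
                             cycle = 0) {
  stopifnot(incidence_rate >= 0)
  p <- as_param_row(params)
  dyn <- arm_dynamics(p, strategy)
  q <- background_death_prob(life, age, sex)
  screen_now <- strategy$arm == "screening" && cycle %% strategy$interval == 0
  plc <- min(1, (1 - exp(-incidence_rate)) * dyn$od)
  fp <- if (screen_now) p$fp_rate_per_screen else 0
  surv <- 1 - q
  m <- matrix(0, 5, 5, dimnames = list(health_states(), health_states()))
  m["healthy", ] <- c(surv * (1 - plc) * (1 - fp),
                      surv * plc * dyn$frac_loc,
                      surv * plc * (1 - dyn$frac_loc),
                      surv * (1 - plc) * fp,
                      q)
  pLd <- lc_death_prob(q, p$hr_death_localized)
  pDd <- lc_death_prob(q, p$hr_death_disseminated)
  m["localized", ] <- c(0, 1 - pLd, 0, 0, pLd)
  m["disseminated", ] <- c(0, 0, 1 - pDd, 0, pDd)
  m["false_positive", ] <- c(1 - q, 0, 0, 0, q)
  m["dead", "dead"] <- 1
  if (any(m < -1e-12) || any(abs(rowSums(m) - 1) > 1e-9)) {
    abort("transition matrix rows must be probabilities summing to 1")
  }
  m
}

# Vectorised cohort-trace engine.
#
# pars: named list whose elements are scalars or length-n vectors (PSA rows).
# Returns per-draw discounted cost/qaly and undiscounted event totals; when
# keep_trace = TRUE (requires n = 1) also the per-cycle trace tibble.
run_arm_engine <- function(pars, strategy, life, rate, entry_age, sex = "total",
                           use_age_bands = FALSE, population = NULL,
                           keep_trace = FALSE, max_age = 110) {
  p <- pars
  n <- max(lengths(p))
  dyn <- arm_dynamics(p, strategy)
  n_cyc <- horizon_cycles(strategy, entry_age, max_age)
  if (n_cyc < 1) abort("entry age beyond model horizon")
  ages <- entry_age + seq_len(n_cyc) - 1
  ages_capped <- pmin(ages, max_age)
  qs <- background_death_prob(life, ages_capped, sex)
  rates <- if (!is.null(population) && use_age_bands) {
    incidence_rate(population, age = ages_capped, use_age_bands = TRUE)
  } else {
    rep(rate, n_cyc)
  }
  dr <- p$discount_rate_annual
  disc <- if (length(unique(dr)) > 1) {
    outer(seq_len(n_cyc) - 1, dr, function(t, r) (1 + r)^(-t))
  } else {
    (1 + dr[1])^-(seq_len(n_cyc) - 1)
  }
  one <- rep(1, n)
  H <- one; L <- 0 * one; D <- 0 * one; FP <- 0 * one; X <- 0 * one
  cost <- 0 * one; qaly <- 0 * one
  tot_fp <- 0 * one; tot_loc <- 0 * one; tot_diss <- 0 * one; screens <- 0 * one
  trace <- if (keep_trace) vector("list", n_cyc)
  for (t in seq_len(n_cyc)) {
    q <- qs[t]
    screen_now <- strategy$arm == "screening" &&
      (t - 1) %% strategy$interval == 0
    plc <- pmin(1, (1 - exp(-rates[t])) * dyn$od)
    surv <- 1 - q
    new_loc <- H * surv * plc * dyn$frac_loc
    new_diss <- H * surv * plc * (1 - dyn$frac_loc)
    new_fp <- if (screen_now) H * surv * (1 - plc) * p$fp_rate_per_screen else 0 * one
    scr <- if (screen_now) H else 0 * one
    v <- if (is.matrix(disc)) disc[t, ] else disc[t]
    cost <- cost + v * (p$cost_usual_annual * H +
                          p$cost_screen_round * scr +
                          p$cost_false_positive * new_fp +
                          p$cost_localized_surgical_oneoff * new_loc +
                          p$cost_localized_postsurgical_per2y / 2 * L +
                          p$cost_disseminated_per2y / 2 * D)
    qaly <- qaly + v * (p$utility_healthy * H + p$utility_localized * L +
                          p$utility_disseminated * D +
                          p$utility_false_positive * FP)
    if (keep_trace) {
      trace[[t]] <- tibble(
        cycle = t - 1L, age = ages[t], healthy = H, localized = L,
        disseminated = D, false_positive = FP, dead = X,
        new_localized = new_loc, new_disseminated = new_diss,
        new_false_positive = new_fp, screens = scr)
    }
    tot_fp <- tot_fp + new_fp; tot_loc <- tot_loc + new_loc
    tot_diss <- tot_diss + new_diss; screens <- screens + scr
    pLd <- 1 - (1 - q)^p$hr_death_localized
    pDd <- 1 - (1 - q)^p$hr_death_disseminated
    X <- X + H * q + L * pLd + D * pDd + FP * q
    H2 <- H * surv * (1 - plc) * (if (screen_now) 1 - p$fp_rate_per_screen else one) +
      FP * surv
    L <- L * (1 - pLd) + new_loc
    D <- D * (1 - pDd) + new_diss
    FP <- new_fp
    H <- H2
    total <- H + L + D + FP + X
    if (any(abs(total - 1) > 1e-6)) {
      abort(sprintf("occupancy drifted from 1 by %.2e at cycle %d",
                    max(abs(total - 1)), t - 1))
    }
  }
  out <- tibble(cost = cost, qaly = qaly, false_positives = tot_fp,
                localized = tot_loc, disseminated = tot_diss,
                screens = screens)
  if (keep_trace) attr(out, "trace") <- list_rbind(trace)
  out
}

#' Run the cohort trace for one strategy
#'
#' Propagates state occupancy over 1-year cycles from model entry to the
#' horizon (age 110 for a lifetime run). Occupancy rows are
#' start-of-cycle; the `new_*` columns count transitions during the cycle
#' and `screens` counts screens performed at the start of the cycle (healthy
#' occupants in screening cycles).
#'
#' `entry` may be a single profile `list(age =, sex =)` or a cohort tibble
#' (columns `age`, `sex`), in which case per-profile traces are
#' occupancy-weighted and averaged (the model is linear in occupancy);
#' subjects younger than the strategy's start age enter at the start age,
#' older subjects at their own age.
#'
#' @param params Parameters (`ascr_params` or one-row tibble).
#' @param strategy A [strategy_spec()].
#' @param incidence Incidence per person-year (scalar) or a `population`
#'   label from [subgroup_incidence()].
#' @param entry Entry profile or cohort tibble; default: everyone enters at
#'   `strategy$start_age` with the life table's `"total"` column.
#' @param life Life table.
#' @param use_age_bands Use age-band incidence rates (only with a
#'   `population` label).
#' @return A trace tibble (class `ascr_trace`): one row per cycle with the
#'   five state occupancies (summing to 1), event counts per person and
#'   screens performed.
#' @examples
#' tr <- run_trace(default_parameters(), strategy_spec("screening", 1),
#'                 incidence = "total")
#' @export
run_trace <- function(params, strategy, incidence = "total", entry = NULL,
                      life = default_life_table(), use_age_bands = FALSE) {
  p <- as_param_row(params)
  pop <- if (is.character(incidence)) incidence
  rate <- if (is.character(incidence)) incidence_rate(incidence) else incidence
  stopifnot(rate >= 0)
  if (is.null(entry)) entry <- list(age = strategy$start_age, sex = "total")
  profiles <- if (is.data.frame(entry)) {
    entry %>%
      mutate(age = pmax(.data$age, strategy$start_age)) %>%
      dplyr::count(.data$age, .data$sex) %>%
      mutate(w = n / sum(n))
  } else {
    tibble(age = max(entry$age, strategy$start_age), sex = entry$sex, w = 1)
  }
  traces <- purrr::pmap(profiles, function(age, sex, w, ...) {
    r <- run_arm_engine(p, strategy, life, rate, entry_age = age, sex = sex,
                        use_age_bands = use_age_bands, population = pop,
                        keep_trace = TRUE)
    attr(r, "trace")
  })
  n_max <- max(vapply(traces, nrow, integer(1)))
  value_cols <- c("healthy", "localized", "disseminated", "false_positive",
                  "dead", "new_localized", "new_disseminated",
                  "new_false_positive", "screens")
  traces <- purrr::map(traces, function(tr) {
    k <- nrow(tr)
    if (k < n_max) {
      # profile fully absorbed before the longest-running profile ends
      pad <- tibble(cycle = seq(k, n_max - 1L),
                    age = tr$age[1] + seq(k, n_max - 1L))
      for (cl in value_cols) pad[[cl]] <- if (cl == "dead") 1 else 0
      tr <- bind_rows(tr, pad)
    }
    tr
  })
  w <- profiles$w / sum(profiles$w)
  out <- traces[[1]][, c("cycle", "age")]
  out$age <- Reduce(`+`, purrr::map2(traces, w, ~ .x$age * .y))
  for (cl in value_cols) {
    out[[cl]] <- Reduce(`+`, purrr::map2(traces, w, ~ .x[[cl]] * .y))
  }
  structure(out, class = c("ascr_trace", class(out)),
            strategy = strategy, params = p)
}
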