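#' Default cohort composition targets
#'
#' Marginal composition of the emulated asbestos-surveillance cohort:
#' 94.8% male; entry-age bands `<60` (23.4%, drawn uniformly on 55-59, the
#' screening start band), `60-75` (73.8%) and `>75` (2.8%, drawn on 75-85);
#' asbestos exposure low/intermediate/high 7.5/67.9/24.5%; smoking
#' never/former/current 30.0/61.5/8.5% (complete-case shares). Pleural-plaque
#' (17%) and asbestosis (2%) prevalences are not tabulated for the source
#' cohort and are package defaults from the surveillance literature; the
#' cost-effectiveness analysis consumes stratum incidence rates, not these
#' flags.
#'
#' @return A named list of proportion vectors and age-band ranges.
#' @export
default_composition <- function() {
  list(
    male = 0.948,
    age_bands = c(lt60 = 0.234, a60_75 = 0.738, gt75 = 0.028),
    age_ranges = list(lt60 = c(55, 59), a60_75 = c(60, 75), gt75 = c(75, 85)),
    smoking = c(never = 0.300, former = 0.615, current = 0.085),
    exposure = c(low = 0.075, intermediate = 0.679, high = 0.246),
    plaques = 0.17,
    asbestosis = 0.02
  )
}

#' Generate a synthetic asbestos-exposed cohort
#'
#' Draws `n` independent subjects matching the marginal composition targets.
#' Attributes are sampled independently across axes (the model consumes
#' stratum-level incidence rates, so joint dependence between axes is not
#' needed); within an age band, entry ages are uniform on the band's range.
#'
#' @param n Number of subjects (0 gives an empty cohort).
#' @param composition Targets as in [default_composition()].
#' @param seed Integer seed for reproducibility.
#' @return A tibble with columns `id`, `age`, `sex`, `smoking`, `exposure`,
#'   `plaques`, `asbestosis`.
#' @examples
#' cohort <- generate_cohort(1000, seed = 1)
#' @export
generate_cohort <- function(n = 14218, composition = default_composition(),
                            seed = NULL) {
  stopifnot(n >= 0)
  comp <- composition
  for (nm in c("age_bands", "smoking", "exposure")) {
    if (abs(sum(comp[[nm]]) - 1) > 1e-6) {
      abort(sprintf("composition$%s proportions must sum to 1", nm))
    }
  }
  for (nm in c("male", "plaques", "asbestosis")) {
    if (comp[[nm]] < 0 || comp[[nm]] > 1) {
      abort(sprintf("composition$%s must be a proportion", nm))
    }
  }
  if (n == 0) {
    return(tibble(id = integer(), age = integer(), sex = character(),
                  smoking = character(), exposure = character(),
                  plaques = logical(), asbestosis = logical()))
  }
  if (!is.null(seed)) set.seed(seed)
  band <- sample(names(comp$age_bands), n, replace = TRUE, prob = comp$age_bands)
  rng <- do.call(rbind, comp$age_ranges[band])
  age <- as.integer(floor(runif(n, rng[, 1], rng[, 2] + 1)))
  tibble(
    id = seq_len(n),
    age = pmin(age, vapply(comp$age_ranges[band], max, numeric(1))),
    sex = ifelse(runif(n) < comp$male, "male", "female"),
    smoking = sample(names(comp$smoking), n, TRUE, comp$smoking),
    exposure = sample(names(comp$exposure), n, TRUE, comp$exposure),
    plaques = runif(n) < comp$plaques,
    asbestosis = runif(n) < comp$asbestosis
  )
}

subject_matches <- function(cohort, spec_row) {
  ok <- rep(TRUE, nrow(cohort))
  if (!spec_row$smoking %in% c("any", NA)) {
    ok <- ok & switch(spec_row$smoking,
      current = cohort$smoking == "current",
      ever = cohort$smoking %in% c("current", "former"),
      never = cohort$smoking == "never",
      cohort$smoking == spec_row$smoking)
  }
  if (!spec_row$exposure %in% c("any", NA)) ok <- ok & cohort$exposure == spec_row$exposure
  if (isTRUE(spec_row$plaques)) ok <- ok & cohort$plaques
  if (isTRUE(spec_row$asbestosis)) ok <- ok & cohort$asbestosis
  ok
}

#' Subset a cohort to a screening-eligibility stratum
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param population A `population` label from [subgroup_incidence()].
#' @return The matching subjects.
#' @export
filter_population <- function(cohort, population) {
  spec <- subgroup_incidence()
  row <- spec[spec$population == population, ]
  if (nrow(row) != 1) abort(sprintf("unknown population '%s'", population))
  cohort[subject_matches(cohort, row), ]
}

#' Simulate lung-cancer incidence in a synthetic cohort
#'
#' Assigns each subject to the first matching stratum of `specs` (an error
#' lists the attributes of any unmatched subject), draws an exponential time
#' to first lung-cancer diagnosis at the stratum rate, censors at `years`,
#' and returns stratum-level events, person-years, the estimated rate and its
#' exact Poisson 95% confidence interval. With `use_age_bands = TRUE` the
#' stratum's age-band rate at entry age is used instead of the all-ages rate.
#'
#' This is the parameter-recovery check for the incidence inputs: the
#' estimated rate should cover the input rate at the nominal level.
#'
#' @param cohort A cohort tibble.
#' @param specs Rows of [subgroup_incidence()] (defaults to the total row).
#' @param years Follow-up duration in years.
#' @param seed Integer seed.
#' @param use_age_bands Use age-band rates at entry age.
#' @return A tibble per stratum: `population`, `n`, `events`, `person_years`,
#'   `rate_per_1000py`, `conf_low`, `conf_high`, `input_rate_per_1000py`.
#' @examples
#' co <- generate_cohort(2000, seed = 1)
#' simulate_incidence(co, years = 17, seed = 2)
#' @export
simulate_incidence <- function(cohort,
                               specs = subgroup_incidence()[subgroup_incidence()$population == "total", ],
                               years = 17, seed = NULL, use_age_bands = FALSE) {
  stopifnot(nrow(cohort) > 0, years > 0)
  if (!is.null(seed)) set.seed(seed)
  assigned <- rep(NA_integer_, nrow(cohort))
  for (i in seq_len(nrow(specs))) {
    m <- subject_matches(cohort, specs[i, ]) & is.na(assigned)
    assigned[m] <- i
  }
  if (anyNA(assigned)) {
    bad <- cohort[is.na(assigned), ][1, ]
    abort(sprintf(
      "subject matches no stratum: smoking=%s exposure=%s plaques=%s asbestosis=%s",
      bad$smoking, bad$exposure, bad$plaques, bad$asbestosis))
  }
  res <- purrr::map(seq_len(nrow(specs)), function(i) {
    idx <- which(assigned == i)
    if (!length(idx)) return(NULL)
    sub <- cohort[idx, ]
    rate <- if (use_age_bands) {
      incidence_rate(specs$population[i], age = sub$age, use_age_bands = TRUE)
    } else {
      rep(specs$all[i] / 1000, nrow(sub))
    }
    tte <- ifelse(rate > 0, rexp(nrow(sub), rate), Inf)
    event <- tte <= years
    py <- pmin(tte, years)
    ev <- sum(event); pys <- sum(py)
    ci <- if (ev > 0 || pys > 0) stats::poisson.test(ev, pys)$conf.int else c(0, Inf)
    tibble(population = specs$population[i], n = nrow(sub), events = ev,
           person_years = pys, rate_per_1000py = 1000 * ev / pys,
           conf_low = 1000 * ci[1], conf_high = 1000 * ci[2],
           input_rate_per_1000py = specs$all[i])
  })
  list_rbind(res)
}
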