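#' Subgroup lung-cancer incidence rates
#'
#' Lung-cancer incidence per 1000 person-years observed in a French
#' post-occupational asbestos-surveillance cohort (about 14,200 subjects
#' followed roughly 17 years), by screening-eligibility stratum and age band.
#' These stratum rates are the SIR input of the transition model: the annual
#' probability of a lung-cancer diagnosis in the healthy state is
#' `1 - exp(-rate)` times the arm's overdiagnosis multiplier.
#'
#' Age bands where no rate was observed (e.g. current smokers above 75) are
#' `NA`; [incidence_rate()] falls back to the 60-75 band for them, with a
#' warning.
#'
#' @return A tibble with one row per stratum: `population` (machine label),
#'   `label`, the defining attributes (`smoking`, `exposure`, `plaques`,
#'   `asbestosis`; `"any"`/`NA` mean unrestricted) and incidence per 1000
#'   person-years for `all` ages, `lt60`, `a60_75`, `gt75`.
#' @examples
#' subgroup_incidence()
#' @export
subgroup_incidence <- function() {
  tibble::tribble(
    ~population,    ~label,                      ~smoking,  ~exposure,      ~plaques, ~asbestosis, ~all, ~lt60, ~a60_75, ~gt75,
    "total",        "Total population",          "any",     "any",          NA,       NA,          2.30, 2.61,  2.21,    2.12,
    "smokers",      "Smokers",                   "current", "any",          NA,       NA,          6.04, 6.41,  5.57,    NA,
    "ever_smokers", "Smokers & former smokers",  "ever",    "any",          NA,       NA,          2.78, 3.22,  2.30,    1.85,
    "high",         "High exposure",             "any",     "high",         NA,       NA,          2.90, 3.03,  2.83,    2.64,
    "intermediate", "Intermediate exposure",     "any",     "intermediate", NA,       NA,          2.20, 2.49,  2.15,    1.91,
    "high_smoker",  "High exposure and smoker",  "current", "high",         NA,       NA,          7.07, 6.36,  7.82,    NA,
    "plaques",      "Pleural plaques",           "any",     "any",          TRUE,     NA,          2.31, 2.42,  2.25,    2.80,
    "asbestosis",   "Asbestosis",                "any",     "any",          NA,       TRUE,        5.00, NA,    6.06,    NA
  )
}

#' Annual lung-cancer incidence rate for a stratum
#'
#' @param population A `population` label from [subgroup_incidence()], or a
#'   numeric rate per 1000 person-years used as-is.
#' @param age Optional integer age(s); if supplied with
#'   `use_age_bands = TRUE`, the age-band rate is returned (bands `<60`,
#'   `60-75`, `>75`), otherwise the all-ages rate.
#' @param use_age_bands Use age-band rates rather than the all-ages rate.
#' @param table Incidence table (defaults to [subgroup_incidence()]).
#' @return Incidence rate per person-year (i.e. the tabulated per-1000 value
#'   divided by 1000), vectorised over `age`.
#' @examples
#' incidence_rate("high_smoker")       # 0.00707
#' incidence_rate("total", age = 58, use_age_bands = TRUE)
#' @export
incidence_rate <- function(population, age = NULL, use_age_bands = FALSE,
                           table = subgroup_incidence()) {
  if (is.numeric(population)) {
    rate1000 <- population
    if (!use_age_bands || is.null(age)) return(rep(rate1000 / 1000, max(1, length(age))))
    return(rep(rate1000 / 1000, length(age)))
  }
  row <- table[table$population == population, ]
  if (nrow(row) != 1) {
    abort(sprintf("no incidence row for population '%s'", population))
  }
  if (!use_age_bands || is.null(age)) {
    return(rep(row$all / 1000, max(1, length(age))))
  }
  band <- ifelse(age < 60, "lt60", ifelse(age <= 75, "a60_75", "gt75"))
  r <- unlist(row[band], use.names = FALSE)
  if (anyNA(r)) {
    warn(sprintf(
      "population '%s' has no observed rate in band(s) %s; falling back to the 60-75 band",
      population, paste(unique(band[is.na(r)]), collapse = ", ")))
    r[is.na(r)] <- row$a60_75
  }
  r / 1000
}
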