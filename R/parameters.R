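#' Default model parameters
#'
#' Builds the base-case parameter set of the screening model: stage fractions
#' at diagnosis for each arm, overdiagnosis hazard ratio, per-screen
#' false-positive rate, stage-specific death hazard ratios, unit costs (euro),
#' utilities and the annual discount rate, each carried as a [dist_spec()]
#' (for inputs that vary in probabilistic sensitivity analysis) or a fixed
#' value.
#'
#' Stage fractions: without screening 18.1% of lung cancers are diagnosed
#' localized (stage I-II) and 81.9% disseminated (stage III-IV, French
#' registry practice); under annual LDCT screening 70.2% / 29.8% (NLST), with
#' an overdiagnosis hazard ratio of 1.13. The per-screen false-positive rate
#' is 1.2% (NELSON nodule management; the NLST rate 23.3% is a scenario
#' variant). Death hazard ratios versus background mortality are 2.68
#' (localized; this single exit transition pools cure, progression and death)
#' and 8.38 (disseminated). Costs: usual-care respiratory care 26 euro/year,
#' screening round 189 euro, localized surgery 13,390 euro one-off,
#' post-surgical care 19,057 euro per 2 years, disseminated care 33,132 euro
#' per 2 years, false-positive work-up 2110 euro. Utilities: healthy 1.0,
#' localized 0.825, disseminated 0.573, false-positive 1.000 (no base-case
#' disutility). Biennial adaptation constants: screen-detected to interval
#' cancer ratio 2.8 (NELSON, 7.69 vs 2.76 per 1000 scans) and a per-screen
#' detection-yield factor of 1.5 (MILD).
#'
#' @return An object of class `ascr_params`: a named list of [dist_spec()]
#'   and scalar values.
#' @examples
#' p <- default_parameters()
#' tidy(p)
#' @export
default_parameters <- function() {
  new_params(list(
    stage_frac_localized_usual    = dist_spec("normal", 0.181, 0.171, 0.191),
    stage_frac_disseminated_usual = dist_spec("normal", 0.819, 0.809, 0.829),
    stage_frac_localized_screen   = dist_spec("normal", 0.702, 0.694, 0.710),
    stage_frac_disseminated_screen = dist_spec("normal", 0.298, 0.290, 0.306),
    hr_overdiagnosis              = 1.13,
    fp_rate_per_screen            = 0.012,
    detected_to_interval_ratio    = 2.8,
    biennial_detection_factor     = 1.5,
    hr_death_localized            = 2.68,
    hr_death_disseminated         = 8.38,
    cost_usual_annual             = dist_spec("gamma", 26, 26, 73),
    cost_screen_round             = dist_spec("gamma", 189, 147, 232),
    cost_localized_surgical_oneoff = dist_spec("gamma", 13390, 6337, 20443),
    cost_localized_postsurgical_per2y = dist_spec("gamma", 19057, 16770, 21429),
    cost_disseminated_per2y       = dist_spec("gamma", 33132, 29357, 34305),
    cost_false_positive           = dist_spec("gamma", 2110, 1716, 2271),
    utility_healthy               = 1.0,
    utility_localized             = dist_spec("beta", 0.825, 0.793, 0.857),
    utility_disseminated          = dist_spec("beta", 0.573, 0.506, 0.640),
    utility_false_positive        = dist_spec("beta", 1.000, 0.970, 1.000),
    discount_rate_annual          = 0.03
  ))
}

param_names <- function() names(default_parameters())

new_params <- function(x) {
  stopifnot(is.list(x))
  obj <- structure(x, class = "ascr_params")
  validate_params(obj)
  obj
}

det_value <- function(x) if (is_dist_spec(x)) x$deterministic else x

validate_params <- function(p) {
  a <- det_value(p$stage_frac_localized_usual)
  b <- det_value(p$stage_frac_disseminated_usual)
  as_ <- det_value(p$stage_frac_localized_screen)
  bs <- det_value(p$stage_frac_disseminated_screen)
  if (abs(a + b - 1) > 1e-9) {
    abort("usual-care stage fractions must sum to 1")
  }
  if (abs(as_ + bs - 1) > 1e-9) {
    abort("screening stage fractions must sum to 1")
  }
  for (nm in c("hr_overdiagnosis", "hr_death_localized", "hr_death_disseminated")) {
    if (det_value(p[[nm]]) < 1) abort(sprintf("%s must be >= 1", nm))
  }
  for (nm in grep("^cost_", names(p), value = TRUE)) {
    if (det_value(p[[nm]]) < 0) abort(sprintf("%s must be >= 0", nm))
  }
  for (nm in grep("^utility_", names(p), value = TRUE)) {
    u <- det_value(p[[nm]])
    if (u < 0 || u > 1) abort(sprintf("%s must be in [0, 1]", nm))
  }
  for (nm in names(p)) {
    if (is_dist_spec(p[[nm]])) validate_dist_spec(p[[nm]], nm)
  }
  invisible(p)
}

#' Override parameter values
#'
#' Returns a copy of `params` with the named entries replaced, for scenario
#' analyses. A scalar replacement for a distributed parameter fixes it at
#' that value; a [dist_spec()] replaces the full specification.
#'
#' @param params An `ascr_params` object.
#' @param ... Named replacements, e.g. `fp_rate_per_screen = 0.233`.
#' @return A modified `ascr_params` object.
#' @examples
#' set_parameters(default_parameters(), fp_rate_per_screen = 0.233)
#' @export
set_parameters <- function(params, ...) {
  stopifnot(inherits(params, "ascr_params"))
  repl <- list(...)
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown)) {
    abort(sprintf("unknown parameter name(s): %s", paste(unknown, collapse = ", ")))
  }
  out <- unclass(params)
  for (nm in names(repl)) {
    val <- repl[[nm]]
    if (is_dist_spec(params[[nm]]) && !is_dist_spec(val)) {
      val <- dist_spec("fixed", val)
    }
    out[[nm]] <- val
  }
  new_params(out)
}

#' @export
print.ascr_params <- function(x, ...) {
  cat("<ascr_params>", length(x), "model parameters\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a parameter set
#'
#' @param x An `ascr_params` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `parameter`, `family`,
#'   `deterministic`, `low`, `high`.
#' @exportS3Method generics::tidy
#' @export
tidy.ascr_params <- function(x, ...) {
  purrr::imap(unclass(x), function(v, nm) {
    if (is_dist_spec(v)) {
      tibble(parameter = nm, family = v$family, deterministic = v$deterministic,
             low = v$low, high = v$high)
    } else {
      tibble(parameter = nm, family = "fixed", deterministic = v,
             low = v, high = v)
    }
  }) %>% list_rbind()
}

#' Deterministic parameter row
#'
#' All distribution specifications collapsed to their deterministic values,
#' as a one-row tibble suitable for the Markov engine. This is the base-case
#' ("all-deterministic") analysis row.
#'
#' @param params An `ascr_params` object.
#' @return A one-row tibble, one column per parameter.
#' @export
deterministic_parameters <- function(params = default_parameters()) {
  vals <- purrr::map(unclass(params), det_value)
  as_tibble(vals)
}

#' Draw parameter sets for probabilistic sensitivity analysis
#'
#' Samples every distributed parameter from its fitted family: gamma costs,
#' beta utilities, normal stage fractions. After independent normal draws the
#' localized/disseminated stage fractions of each arm are renormalized to sum
#' to one; sampled utilities are clipped to `[0, 1]` and costs to `>= 0`.
#' Fixed parameters repeat their deterministic value.
#'
#' @param params An `ascr_params` object.
#' @param n_draws Number of parameter sets.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A tibble with `n_draws` rows and one column per parameter.
#' @examples
#' draws <- draw_parameters(default_parameters(), n_draws = 100, seed = 1)
#' @export
draw_parameters <- function(params = default_parameters(), n_draws = 10000,
                            seed = NULL) {
  stopifnot(inherits(params, "ascr_params"), n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  cols <- purrr::imap(unclass(params), function(v, nm) {
    if (!is_dist_spec(v)) return(rep(v, n_draws))
    x <- draw_dist(fit_distribution(v, nm), n_draws)
    if (grepl("^utility_", nm)) x <- pmin(pmax(x, 0), 1)
    if (grepl("^cost_", nm)) x <- pmax(x, 0)
    x
  })
  out <- as_tibble(cols)
  # renormalize stage-fraction pairs per arm
  su <- out$stage_frac_localized_usual + out$stage_frac_disseminated_usual
  out$stage_frac_localized_usual <- out$stage_frac_localized_usual / su
  out$stage_frac_disseminated_usual <- out$stage_frac_disseminated_usual / su
  ss <- out$stage_frac_localized_screen + out$stage_frac_disseminated_screen
  out$stage_frac_localized_screen <- out$stage_frac_localized_screen / ss
  out$stage_frac_disseminated_screen <- out$stage_frac_disseminated_screen / ss
  out
}

#' Read a parameter configuration file
#'
#' Loads a YAML file in which each key is a parameter name and each value is
#' either a scalar or a mapping with `family`, `deterministic`, `low`, `high`.
#' The bundled default configuration
#' (`system.file("extdata", "default_params.yaml", package = "asbscreen")`)
#' reproduces [default_parameters()] exactly.
#'
#' @param path Path to a YAML file.
#' @return An `ascr_params` object.
#' @export
read_parameter_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- param_names()
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("unknown parameter key(s) in %s: %s", path,
                  paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(known, names(raw))
  if (length(missing)) {
    abort(sprintf("missing parameter key(s) in %s: %s", path,
                  paste(missing, collapse = ", ")))
  }
  lst <- purrr::imap(raw, function(v, nm) {
    if (is.list(v)) {
      dist_spec(v$family, v$deterministic,
                v$low %||% v$deterministic, v$high %||% v$deterministic)
    } else {
      v
    }
  })
  new_params(lst[known])
}

#' Write a parameter configuration file
#'
#' Inverse of [read_parameter_config()].
#'
#' @param params An `ascr_params` object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_parameter_config <- function(params, path) {
  stopifnot(inherits(params, "ascr_params"))
  raw <- purrr::map(unclass(params), function(v) {
    if (is_dist_spec(v)) {
      list(family = v$family, deterministic = v$deterministic,
           low = v$low, high = v$high)
    } else v
  })
  yaml::write_yaml(raw, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
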