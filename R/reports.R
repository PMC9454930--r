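analysis_config_keys <- c(
  "seed", "populations", "start_ages", "intervals", "start_age", "horizon",
  "n_draws", "thresholds", "psa_population", "psa_interval",
  "params", "life_table", "cohort_n"
)

# atomically write a data frame as CSV with a seed-stamped header comment:
# the file is written to a temporary name in the target directory and then
# renamed, so readers never observe a partial file.
write_report_csv <- function(df, name, out_dir, seed) {
  tmp <- file.path(out_dir, paste0(".", name, ".tmp"))
  final <- file.path(out_dir, name)
  con <- file(tmp, "w")
  on.exit(try(close(con), silent = TRUE), add = TRUE)
  writeLines(sprintf("# asbscreen run; seed %s", seed %||% "none"), con)
  utils::write.table(as.data.frame(df), con, sep = ",", row.names = FALSE,
                     qmethod = "double")
  close(con)
  if (!file.rename(tmp, final)) abort(sprintf("could not write %s", final))
  final
}

#' Run the full screening analysis and write a report bundle
#'
#' Drives every analysis of the package from one configuration: the
#' deterministic base case for each population/interval combination, the
#' probabilistic sensitivity analysis and its acceptability curve, the
#' one-way tornado analysis, the deterministic scenario grid and the cohort
#' traces of the featured strategy. All outputs are plain CSV files stamped
#' with the run seed, written atomically (write-then-rename), plus a
#' `manifest.json` listing each file's MD5 hash so a re-run with the same
#' configuration and seed can be verified byte-for-byte.
#'
#' `config` may be a named list or the path of a YAML file with any of the
#' keys `seed`, `populations`, `start_ages`, `intervals`, `start_age`,
#' `horizon`, `n_draws`, `thresholds`, `psa_population`, `psa_interval`,
#' `params` (path to a parameter YAML, see [read_parameter_config()]),
#' `life_table` (path, see [read_life_table()]) and `cohort_n`. An unknown
#' key is an error before any computation starts.
#'
#' @param config Named list or YAML path (see Details).
#' @param out_dir Output directory, created if missing.
#' @return An `ascr_analysis` list (invisibly): the result objects plus the
#'   manifest of written files.
#' @examples
#' \donttest{
#' res <- run_analysis(list(seed = 1, n_draws = 200), out_dir = tempfile())
#' }
#' @export
run_analysis <- function(config = list(), out_dir = tempfile("asbscreen-")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), analysis_config_keys)
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  seed <- config$seed %||% 1L
  populations <- config$populations %||% c("total", "high_smoker")
  start_ages <- config$start_ages %||% c(50, 55, 60)
  intervals <- config$intervals %||% c(1, 2)
  start_age <- config$start_age %||% 55
  horizon <- config$horizon %||% "lifetime"
  n_draws <- config$n_draws %||% 10000
  thresholds <- config$thresholds %||% seq(0, 150000, by = 5000)
  psa_population <- config$psa_population %||% "high_smoker"
  psa_interval <- config$psa_interval %||% 2
  cohort_n <- config$cohort_n %||% 14218
  params <- if (!is.null(config$params)) {
    read_parameter_config(config$params)
  } else {
    default_parameters()
  }
  life <- if (!is.null(config$life_table)) {
    read_life_table(config$life_table)
  } else {
    default_life_table()
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  basecase <- tidyr::expand_grid(population = populations,
                                 interval = intervals) %>%
    purrr::pmap(function(population, interval) {
      cea <- cea_screening(population, interval, start_age, horizon,
                           params = params, life = life, cohort_n = cohort_n)
      ev <- cea$events$screening
      tibble(population = population, interval = interval,
             cost_usual = cea$arms$cost[1], qaly_usual = cea$arms$qaly[1],
             cost_screen = cea$arms$cost[2], qaly_screen = cea$arms$qaly[2]) %>%
        bind_cols(cea$incremental) %>%
        mutate(false_positives = ev$false_positives,
               localized = ev$localized, disseminated = ev$disseminated,
               screens = ev$screens)
    }) %>% list_rbind()

  psa <- run_psa(psa_population, psa_interval, start_age, horizon,
                 params = params, n_draws = n_draws, seed = seed, life = life)
  ceac_tbl <- ceac(psa, thresholds = thresholds)
  tornado <- tornado_analysis(params, psa_population, psa_interval,
                              start_age, horizon, life = life)
  grid <- scenario_grid(populations = populations, start_ages = start_ages,
                        intervals = intervals, params = params, life = life,
                        horizon = horizon)
  trace_u <- run_trace(params, strategy_spec("usual_care", NA, start_age, horizon),
                       incidence = psa_population, life = life)
  trace_s <- run_trace(params,
                       strategy_spec("screening", psa_interval, start_age, horizon),
                       incidence = psa_population, life = life)

  files <- c(
    write_report_csv(basecase, "basecase.csv", out_dir, seed),
    write_report_csv(psa$summary, "psa_summary.csv", out_dir, seed),
    write_report_csv(ceac_tbl, "ceac.csv", out_dir, seed),
    write_report_csv(tibble::as_tibble(tornado), "tornado.csv", out_dir, seed),
    write_report_csv(grid, "scenario_grid.csv", out_dir, seed),
    write_report_csv(trace_u, "trace_usual_care.csv", out_dir, seed),
    write_report_csv(trace_s, "trace_screening.csv", out_dir, seed)
  )
  manifest <- tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = unname(file.size(files))
  )
  tmp <- file.path(out_dir, ".manifest.json.tmp")
  jsonlite::write_json(
    list(seed = seed, files = manifest), tmp,
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, file.path(out_dir, "manifest.json"))

  out <- structure(list(
    basecase = basecase, psa = psa, ceac = ceac_tbl, tornado = tornado,
    scenario_grid = grid, traces = list(usual_care = trace_u,
                                        screening = trace_s),
    manifest = manifest, out_dir = out_dir, seed = seed
  ), class = "ascr_analysis")
  invisible(out)
}

#' @export
print.ascr_analysis <- function(x, ...) {
  cat(sprintf("<ascr_analysis> seed %s, outputs in %s\n", x$seed, x$out_dir))
  print(as.data.frame(x$manifest), row.names = FALSE)
  invisible(x)
}
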