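#' Read a scenario configuration file
#'
#' Scenario files are JSON with fields `variant`, optional `params`
#' overrides (reference units: hormone rates per minute, mass rates per
#' day), `protocol` (`type` one of `"constant"`, `"step"`, `"step_decay"`
#' plus its fields), `t_start`/`t_end` (days), optional `crh_tests` (list
#' of `{t_inj, dose, width, window}`), optional `test_days`, and optional
#' `solver` (`rtol`, `atol`, `hmax`, `grid_hours`). Packaged examples live
#' under `system.file("extdata", package = "hpaxis")`.
#'
#' @param path Path to a JSON scenario file.
#' @return A list of class `hpa_scenario` with resolved `model`,
#'   `protocol`, `span`, `crh_tests`, `test_days`, `solver`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  variant <- cfg$variant %||% "full_mass"
  params <- do.call(hpa_params, as.list(cfg$params %||% list()))
  pr <- cfg$protocol %||% list(type = "constant")
  protocol <- switch(pr$type %||% "constant",
    constant = protocol_constant(pr$u %||% 1),
    step = protocol_step(u = pr$u %||% 4, start = pr$start %||% 0,
                         end = pr$end %||% 90,
                         baseline = pr$baseline %||% 1),
    step_decay = protocol_step_decay(u = pr$u %||% 4, start = pr$start %||% 0,
                                     duration = pr$duration %||% 90,
                                     half_life = pr$half_life %||% 30,
                                     baseline = pr$baseline %||% 1),
    stop("unknown protocol type `", pr$type, "` in ", path, call. = FALSE)
  )
  crh_tests <- list()
  if (!is.null(cfg$crh_tests)) {
    ct <- cfg$crh_tests
    if (is.data.frame(ct)) ct <- split(ct, seq_len(nrow(ct)))
    crh_tests <- lapply(ct, function(s) {
      crh_spec(t_inj = s$t_inj %||% 0, dose = s$dose, width = s$width,
               window = s$window %||% 180, params = params)
    })
  }
  solver <- cfg$solver %||% list()
  structure(
    list(variant = variant, model = hpa_model(variant, params),
         params = params, protocol = protocol,
         t_start = cfg$t_start %||% 0, t_end = cfg$t_end %||% 300,
         crh_tests = crh_tests,
         test_days = cfg$test_days,
         K_GR_values = cfg$K_GR_values,
         solver = list(rtol = solver$rtol %||% 1e-8,
                       atol = solver$atol %||% 1e-10,
                       hmax = solver$hmax %||% 10,
                       grid_hours = solver$grid_hours %||% 1)),
    class = "hpa_scenario"
  )
}

#' Run a scenario configuration
#'
#' @param scenario An `hpa_scenario` from [read_scenario()] (or a path).
#' @return An `hpa_trajectory`.
#' @export
run_scenario <- function(scenario) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  stopifnot(inherits(scenario, "hpa_scenario"))
  s <- scenario$solver
  simulate_hpa(scenario$model, scenario$protocol,
               t_start = scenario$t_start, t_end = scenario$t_end,
               crh_tests = scenario$crh_tests,
               rtol = s$rtol, atol = s$atol, hmax = s$hmax,
               grid_hours = s$grid_hours)
}
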