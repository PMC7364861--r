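#' Simulate a CRH stimulation test from a state snapshot
#'
#' Integrates the model from `snapshot` over the observation window with
#' the exogenous-CRH boxcar of `spec`, at minute resolution, while the
#' background input keeps following `protocol` (the test adds CRH to the
#' running scenario; it does not reset the stressor). The test is a
#' counterfactual probe: the snapshot itself is never modified.
#'
#' @param model An [hpa_model()] or variant id string.
#' @param snapshot Named state vector at the injection time (a trajectory
#'   row, a model baseline, or a [steady_state()] row). A missing `x1E`
#'   is taken as 0.
#' @param protocol Background input protocol during the test.
#' @param spec A [crh_spec()]; its `t_inj` places the test on the
#'   protocol's clock.
#' @param mode `"peak"` (default): response = maximum absolute hormone
#'   level over the window; `"increment"`: maximum minus the pre-injection
#'   level.
#' @param params Parameters used when `model` is a string.
#' @param rtol,atol,hmax Solver settings (see [simulate_hpa()]).
#' @return An object of class `hpa_crh_test`: list with `peaks` (named
#'   vector `acth`, `cortisol`), `trace` (minute-resolution tibble),
#'   `snapshot`, `spec`, `mode`.
#' @examples
#' m <- hpa_model("full_mass")
#' ctl <- run_crh_test(m, m$baseline)
#' ctl$peaks
#' @export
run_crh_test <- function(model, snapshot, protocol = protocol_constant(),
                         spec = crh_spec(), mode = c("peak", "increment"),
                         params = hpa_params(),
                         rtol = 1e-8, atol = 1e-10, hmax = 10) {
  mode <- match.arg(mode)
  if (is.character(model)) model <- hpa_model(model, params)
  snapshot <- as_state(model, snapshot)
  traj <- simulate_hpa(model, protocol,
                       t_start = spec$t_inj,
                       t_end = spec$t_inj + spec$window / 1440,
                       init = snapshot, crh_tests = list(spec),
                       rtol = rtol, atol = atol, hmax = hmax,
                       grid_hours = 1 / 60)
  tr <- traj$data
  pre <- c(acth = snapshot[["x2"]], cortisol = snapshot[["x3"]])
  peaks <- c(acth = max(tr$x2), cortisol = max(tr$x3))
  if (mode == "increment") peaks <- peaks - pre
  structure(list(peaks = peaks, pre = pre, trace = tr,
                 snapshot = snapshot, spec = spec, mode = mode),
            class = "hpa_crh_test")
}

# coerce a trajectory row / named vector / steady_state row to a model state
as_state <- function(model, x) {
  if (is.data.frame(x)) x <- unlist(x[1, intersect(names(x), model$layout)])
  if (is.null(names(x))) {
    stopifnot(length(x) == length(model$layout))
    return(stats::setNames(as.numeric(x), model$layout))
  }
  st <- model$baseline
  keep <- intersect(names(x), model$layout)
  st[keep] <- x[keep]
  st
}

#' Control CRH test at the basal steady state
#'
#' The reference test against which all response ratios are formed: the
#' model sitting at its baseline under basal input `u = 1`.
#'
#' @inheritParams run_crh_test
#' @return An `hpa_crh_test`.
#' @export
control_crh_test <- function(model, spec = crh_spec(),
                             mode = c("peak", "increment"),
                             params = hpa_params(),
                             rtol = 1e-8, atol = 1e-10, hmax = 10) {
  if (is.character(model)) model <- hpa_model(model, params)
  spec$t_inj <- 0
  run_crh_test(model, model$baseline, protocol_constant(1), spec,
               mode = mode, rtol = rtol, atol = atol, hmax = hmax)
}

#' Response ratio of a CRH test relative to control
#'
#' Peak hormone responses of the case test divided componentwise by the
#' control peaks. Values below 1 are blunted responses.
#'
#' @param case,control `hpa_crh_test` objects (same `mode`).
#' @return One-row tibble with `acth_ratio` and `cortisol_ratio`.
#' @export
response_ratio <- function(case, control) {
  stopifnot(inherits(case, "hpa_crh_test"), inherits(control, "hpa_crh_test"))
  if (!identical(case$mode, control$mode)) {
    stop("case and control tests use different response modes", call. = FALSE)
  }
  if (any(control$peaks <= 0)) {
    stop("control peaks must be strictly positive to form ratios", call. = FALSE)
  }
  tibble::tibble(acth_ratio = case$peaks[["acth"]] / control$peaks[["acth"]],
                 cortisol_ratio = case$peaks[["cortisol"]] / control$peaks[["cortisol"]])
}

#' CRH-test response timeline over a scenario
#'
#' Runs the scenario once, then at each scheduled day clones the state and
#' simulates a counterfactual CRH test under the ongoing protocol,
#' recording peak-response ratios against a single basal control. This is
#' the model's prediction for CRH tests administered on different days
#' during and after a stressor.
#'
#' @inheritParams run_crh_test
#' @param test_days Numeric vector of test days (default: daily from 0 to
#'   `t_end`).
#' @param t_end Scenario span in days.
#' @param grid_hours Sampling interval of the underlying scenario run.
#' @return An object of class `hpa_timeline`: tibble with columns `day`,
#'   `acth_ratio`, `cortisol_ratio`, `lam_C`, `lam_A` (gland-mass scalings
#'   at the test day; 1 for constant-mass variants), plus attributes
#'   `control` (peaks), `stress_end`, `variant`.
#' @examples
#' \donttest{
#' tl <- response_timeline("full_mass", protocol_step(u = 4, end = 90),
#'                         test_days = seq(0, 200, by = 10))
#' }
#' @export
response_timeline <- function(model, protocol = protocol_step(),
                              test_days = NULL, t_end = 300,
                              spec = crh_spec(), mode = c("peak", "increment"),
                              params = hpa_params(),
                              rtol = 1e-8, atol = 1e-10, hmax = 10,
                              grid_hours = 1) {
  mode <- match.arg(mode)
  if (is.character(model)) model <- hpa_model(model, params)
  if (is.null(test_days)) test_days <- seq(0, t_end, by = 1)
  if (any(test_days < 0) || any(test_days > t_end)) {
    stop("`test_days` must lie within [0, t_end]", call. = FALSE)
  }
  traj <- simulate_hpa(model, protocol, t_start = 0, t_end = t_end,
                       rtol = rtol, atol = atol, hmax = hmax,
                       grid_hours = grid_hours, extra_times = test_days)
  control <- control_crh_test(model, spec, mode = mode,
                              rtol = rtol, atol = atol, hmax = hmax)
  rows <- purrr::map(test_days, function(day) {
    i <- which.min(abs(traj$data$time - day))
    snap <- as_state(model, traj$data[i, ])
    s <- spec
    s$t_inj <- day
    case <- run_crh_test(model, snap, protocol, s, mode = mode,
                         rtol = rtol, atol = atol, hmax = hmax)
    rr <- response_ratio(case, control)
    tibble::tibble(day = day, acth_ratio = rr$acth_ratio,
                   cortisol_ratio = rr$cortisol_ratio,
                   lam_C = if ("C" %in% model$layout) snap[["C"]] else 1,
                   lam_A = if ("A" %in% model$layout) snap[["A"]] else 1)
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
            control = control$peaks, stress_end = protocol_stress_end(protocol),
            variant = model$variant, spec = spec, mode = mode,
            trajectory = traj,
            class = c("hpa_timeline", class(out)))
}

#' Classify withdrawal phases along a response timeline
#'
#' Labels each test day and merges contiguous runs into intervals.
#' During the stressor: `onset` while responses are still elevated
#' (either ratio above the normality band), `adapted` once gland growth
#' has pulled the responses back. After the stressor: `EW` (early
#' withdrawal; cortisol ratio above the band), `IW` (intermediate
#' withdrawal; cortisol ratio inside the band while the ACTH ratio is
#' below the blunting threshold — the signature dysregulation), `LW`
#' (late withdrawal; both ratios inside the band), and `other` for the
#' remaining transitional samples.
#'
#' The band and threshold are modelling decisions (the published figures
#' carry no numeric cutoffs): the default band of 5 percent sits well
#' inside the visual separation of the phases while staying robust to the
#' ~1.5 percent feedback-normalization ambiguity, and blunting is declared
#' below a 0.9 ratio.
#'
#' @param timeline An `hpa_timeline`.
#' @param normal_band Half-width of the normality band around 1.
#' @param blunt_threshold ACTH ratio below which a response counts as
#'   blunted.
#' @return An object of class `hpa_phases`: list with `labels` (per-day
#'   tibble) and `intervals` (tibble `phase`, `start`, `end`, `duration`).
#' @export
classify_phases <- function(timeline, normal_band = 0.05,
                            blunt_threshold = 0.9) {
  stopifnot(inherits(timeline, "hpa_timeline"))
  if (nrow(timeline) == 0) stop("empty timeline", call. = FALSE)
  if (normal_band <= 0 || normal_band >= 1 ||
      blunt_threshold <= 0 || blunt_threshold >= 1) {
    stop("`normal_band` and `blunt_threshold` must lie in (0, 1)", call. = FALSE)
  }
  stress_end <- attr(timeline, "stress_end")
  inb <- function(r) abs(r - 1) <= normal_band
  lab <- purrr::map2_chr(timeline$acth_ratio, timeline$cortisol_ratio,
                         function(a, c3) {
                           if (a > 1 + normal_band || c3 > 1 + normal_band) "elevated"
                           else "settled"
                         })
  post <- timeline$day > stress_end
  lab[!post & lab == "elevated"] <- "onset"
  lab[!post & lab == "settled"] <- "adapted"
  for (i in which(post)) {
    a <- timeline$acth_ratio[i]
    c3 <- timeline$cortisol_ratio[i]
    lab[i] <-
      if (c3 > 1 + normal_band) "EW"
      else if (inb(c3) && a < blunt_threshold) "IW"
      else if (inb(c3) && inb(a)) "LW"
      else "other"
  }
  labels <- tibble::tibble(day = timeline$day, phase = lab)
  runs <- rle(lab)
  stops <- cumsum(runs$lengths)
  starts <- c(1, utils::head(stops, -1) + 1)
  intervals <- tibble::tibble(
    phase = runs$values,
    start = timeline$day[starts],
    end = timeline$day[stops]
  )
  intervals$duration <- intervals$end - intervals$start
  structure(list(labels = labels, intervals = intervals,
                 normal_band = normal_band, blunt_threshold = blunt_threshold,
                 stress_end = stress_end),
            class = "hpa_phases")
}

#' @export
print.hpa_phases <- function(x, ...) {
  cat("<hpa_phases> band ±", x$normal_band, ", blunting < ",
      x$blunt_threshold, "\n", sep = "")
  print(x$intervals)
  invisible(x)
}

#' Total duration of one phase
#'
#' @param phases An `hpa_phases` object.
#' @param phase Phase label, e.g. `"IW"`.
#' @return Summed duration in days (0 when the phase never occurs).
#' @export
phase_duration <- function(phases, phase = "IW") {
  stopifnot(inherits(phases, "hpa_phases"))
  sum(phases$intervals$duration[phases$intervals$phase == phase])
}

#' Post-stress recovery order of the three hormones
#'
#' For each hormone, the first post-stress time at which it enters the
#' tolerance band around baseline and stays inside for the remainder of
#' the trajectory (sustained entry). The circuit's structure forces CRH
#' and cortisol to recover together, before ACTH.
#'
#' @param traj An `hpa_trajectory` covering the recovery.
#' @param tol Band half-width around baseline (default 0.1). The default
#'   sits just above the at-most-9-percent residual wobble that CRH and
#'   cortisol show after their first simultaneous normalization, so the
#'   sustained-entry time reflects that first normalization rather than
#'   the tail of the wobble.
#' @param after Start of the recovery period in days (default: the
#'   protocol's stress end; the trajectory start for constant protocols).
#' @return Tibble with columns `hormone` (`x1`, `x3`, `x2`), `time`
#'   (days; `NA` if unrecovered within the span), `recovered`.
#' @export
recovery_order <- function(traj, tol = 0.1, after = NULL) {
  stopifnot(inherits(traj, "hpa_trajectory"))
  if (is.null(after)) after <- protocol_stress_end(traj$protocol)
  if (!is.finite(after)) after <- min(traj$data$time)
  sub <- traj$data[traj$data$time >= after, ]
  if (nrow(sub) < 2) stop("trajectory does not cover the recovery period",
                          call. = FALSE)
  one <- function(var) {
    v <- sub[[var]]
    t <- sub$time
    out_idx <- which(abs(v - 1) > tol)
    if (length(out_idx) == 0) {
      return(tibble::tibble(hormone = var, time = t[1], recovered = TRUE))
    }
    i <- max(out_idx)
    if (i == length(v)) {
      return(tibble::tibble(hormone = var, time = NA_real_, recovered = FALSE))
    }
    level <- if (v[i] > 1) 1 + tol else 1 - tol
    sf <- stats::splinefun(t, v, method = "fmm")
    tc <- tryCatch(
      stats::uniroot(function(x) sf(x) - level, c(t[i], t[i + 1]),
                     tol = 1e-6 * max(1, abs(t[i + 1])))$root,
      error = function(e) t[i + 1]
    )
    tibble::tibble(hormone = var, time = tc, recovered = TRUE)
  }
  dplyr::bind_rows(lapply(c("x1", "x3", "x2"), one))
}

#' Gland-mass product at the first simultaneous normalization
#'
#' Locates the first post-stress time at which CRH and cortisol are both
#' within `tol` of baseline and evaluates the product of the gland
#' functional masses there. Because CRH and cortisol are functions of the
#' product `A*C` on the fast timescale, the product must equal 1 at that
#' event (the \eqn{\lambda_A \lambda_C = 1} identity); this function
#' measures it from the simulation.
#'
#' @param traj An `hpa_trajectory`.
#' @param tol Normalization tolerance (default 1e-3).
#' @param after Start of the search window (default: protocol stress end).
#' @return One-row tibble with `time` (days), `product` (`A*C`; 1 for
#'   constant-mass variants), `lam_C`, `lam_A`, and `found`. When the
#'   event is absent within the span, `found` is `FALSE` and the values
#'   are `NA` (reported, not an error).
#' @export
mass_normalization_product <- function(traj, tol = 1e-3, after = NULL) {
  stopifnot(inherits(traj, "hpa_trajectory"))
  if (is.null(after)) after <- protocol_stress_end(traj$protocol)
  if (!is.finite(after)) after <- min(traj$data$time)
  sub <- traj$data[traj$data$time >= after, ]
  dev <- pmax(abs(sub$x1 - 1), abs(sub$x3 - 1))
  idx <- which(dev < tol)
  if (length(idx) == 0) {
    return(tibble::tibble(time = NA_real_, product = NA_real_,
                          lam_C = NA_real_, lam_A = NA_real_, found = FALSE))
  }
  i <- idx[1]
  t <- sub$time
  # refine the entry time of max(|x1-1|, |x3-1|) into the band
  tev <- t[i]
  if (i > 1) {
    sfd <- stats::splinefun(t, dev, method = "fmm")
    tev <- tryCatch(
      stats::uniroot(function(x) sfd(x) - tol, c(t[i - 1], t[i]),
                     tol = 1e-8 * max(1, abs(t[i])))$root,
      error = function(e) t[i]
    )
  }
  has_mass <- all(c("C", "A") %in% names(sub))
  if (has_mass) {
    lam_C <- stats::splinefun(t, sub$C, method = "fmm")(tev)
    lam_A <- stats::splinefun(t, sub$A, method = "fmm")(tev)
  } else {
    lam_C <- 1
    lam_A <- 1
  }
  tibble::tibble(time = tev, product = lam_A * lam_C,
                 lam_C = lam_C, lam_A = lam_A, found = TRUE)
}
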