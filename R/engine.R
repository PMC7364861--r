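#' Simulate a model variant over a scenario
#'
#' Integrates the chosen circuit from an initial state (default: the
#' variant's baseline, the steady state at basal input `u = 1`) under an
#' input protocol, with optional CRH-test boxcar infusions. Every
#' discontinuity of `u(t)` and every boxcar edge is an integration
#' breakpoint: the adaptive solver is restarted there so no step straddles
#' a jump. The result is deterministic and reproducible bit-for-bit for a
#' given configuration.
#'
#' Default tolerances are tight (`rtol = 1e-8`) because downstream metrics
#' compare baseline-crossing times across a ~5000-fold timescale
#' separation (minutes-scale hormones vs. week-scale masses). `hmax = 10`
#' minutes keeps the explicit solver inside its stability interval for the
#' fastest hormone rate.
#'
#' @param model An [hpa_model()] object, or a variant id string.
#' @param protocol An `hpa_protocol` (see [protocols]).
#' @param t_start,t_end Simulation span in days.
#' @param init Optional named initial state (defaults to the model
#'   baseline). Components may be given in any order; a missing `x1E` is
#'   taken as 0.
#' @param crh_tests Optional list of [crh_spec()] doses applied during the
#'   run.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param hmax Maximum step, minutes.
#' @param grid_hours Output sampling interval in hours outside CRH-test
#'   windows (default 1); inside each test window sampling is 1 minute.
#' @param extra_times Additional output times (days) guaranteed to appear
#'   in the grid, e.g. scheduled snapshot days.
#' @param params Parameters used when `model` is given as a string.
#' @return An object of class `hpa_trajectory`: a list with `data` (tibble,
#'   `time` in days plus one column per state variable), `variant`,
#'   `params`, `protocol`, `crh_tests`, and `solver` settings.
#' @examples
#' traj <- simulate_hpa("classic", protocol_constant(1), t_end = 1)
#' tail(traj$data)
#' @export
simulate_hpa <- function(model, protocol = protocol_constant(),
                         t_start = 0, t_end = 300, init = NULL,
                         crh_tests = list(),
                         rtol = 1e-8, atol = 1e-10, hmax = 10,
                         grid_hours = 1, extra_times = NULL,
                         params = hpa_params()) {
  if (is.character(model)) model <- hpa_model(model, params)
  stopifnot(inherits(model, "hpa_model"), inherits(protocol, "hpa_protocol"))
  if (inherits(crh_tests, "hpa_crh_spec")) crh_tests <- list(crh_tests)
  if (!is.finite(t_start) || !is.finite(t_end) || t_end <= t_start) {
    stop("need finite `t_start` < `t_end` (days)", call. = FALSE)
  }
  if (rtol <= 0 || atol <= 0 || hmax <= 0) {
    stop("solver tolerances and `hmax` must be positive", call. = FALSE)
  }

  y0 <- model$baseline
  if (!is.null(init)) {
    if (is.null(names(init))) {
      stopifnot(length(init) %in% c(length(model$layout), length(model$layout) - 1))
      y0[seq_along(init)] <- init
    } else {
      unknown <- setdiff(names(init), model$layout)
      if (length(unknown) > 0) {
        stop("initial-state component(s) not in the ", model$variant,
             " layout: ", paste(unknown, collapse = ", "), call. = FALSE)
      }
      y0[names(init)] <- init
    }
  }
  if (any(!is.finite(y0)) || any(y0[setdiff(model$layout, "x1E")] <= 0)) {
    stop("initial state must be strictly positive (x1E may be 0)", call. = FALSE)
  }

  T0 <- t_start * 1440
  T1 <- t_end * 1440

  # breakpoints: protocol segment edges + boxcar edges, interior to the span
  bps <- numeric(0)
  if (nrow(protocol) > 0) {
    bps <- c(bps, protocol$start * 1440,
             protocol$end[is.finite(protocol$end)] * 1440)
  }
  for (spec in crh_tests) {
    stopifnot(inherits(spec, "hpa_crh_spec"))
    bps <- c(bps, spec$t_inj * 1440, spec$t_inj * 1440 + spec$width)
  }
  bps <- sort(unique(bps[bps > T0 + 1e-9 & bps < T1 - 1e-9]))

  # output grid: coarse everywhere, minute resolution inside test windows
  grid <- seq(T0, T1, by = grid_hours * 60)
  for (spec in crh_tests) {
    a <- spec$t_inj * 1440
    b <- min(a + spec$window, T1)
    if (b > T0 && a < T1) grid <- c(grid, seq(max(a, T0), b, by = 1))
  }
  if (!is.null(extra_times)) grid <- c(grid, extra_times * 1440)
  grid <- sort(unique(round(c(grid, bps, T1), 6)))
  grid <- grid[grid >= T0 & grid <= T1]

  edges <- c(T0, bps, T1)
  pars <- cpp_pars(model)
  vcode <- variant_code(model$variant)
  rows <- vector("list", length(edges) - 1)
  y <- as.numeric(y0)
  nsteps <- 0
  for (k in seq_len(length(edges) - 1)) {
    a <- edges[k]; b <- edges[k + 1]
    mid <- (a + b) / 2
    useg <- piece_input(protocol, mid / 1440)
    dose <- 0
    for (spec in crh_tests) dose <- dose + crh_dose_at(spec, mid)
    tout <- grid[grid > a + 1e-9 & grid <= b + 1e-9]
    res <- hpa_integrate_piece(vcode, y, a, b,
                               useg$type, useg$u0, useg$ubase, useg$tau,
                               useg$t0, dose, pars, rtol, atol, hmax, tout)
    m <- res$states
    colnames(m) <- model$layout
    rows[[k]] <- cbind(time = tout, m)
    y <- res$yend
    nsteps <- nsteps + res$nsteps
  }
  states <- do.call(rbind, rows)
  data <- tibble::as_tibble(rbind(
    c(time = T0, stats::setNames(as.numeric(y0), model$layout)),
    states
  ))
  data$time <- data$time / 1440

  structure(
    list(data = data, variant = model$variant, params = model$params,
         protocol = protocol, crh_tests = crh_tests,
         solver = list(rtol = rtol, atol = atol, hmax = hmax,
                       grid_hours = grid_hours, nsteps = nsteps),
         model = model),
    class = "hpa_trajectory"
  )
}

# smooth input description for one breakpoint-free piece, at time t (days):
# type 0 constant u0; type 1 exponential relaxation toward ubase
piece_input <- function(protocol, t) {
  base <- attr(protocol, "baseline")
  for (i in seq_len(nrow(protocol))) {
    seg <- protocol[i, ]
    if (t >= seg$start && t < seg$end) {
      if (seg$type == "step") {
        return(list(type = 0L, u0 = seg$u, ubase = seg$u, tau = 1, t0 = 0))
      }
      return(list(type = 1L, u0 = seg$u, ubase = base,
                  tau = seg$half_life * 1440 / log(2), t0 = seg$start * 1440))
    }
  }
  list(type = 0L, u0 = base, ubase = base, tau = 1, t0 = 0)
}

#' @export
print.hpa_trajectory <- function(x, ...) {
  cat("<hpa_trajectory>", x$variant, "\n")
  cat(sprintf("  span: %.4g .. %.4g days, %d samples, %g solver steps\n",
              min(x$data$time), max(x$data$time), nrow(x$data),
              x$solver$nsteps))
  print(utils::tail(x$data, 3))
  invisible(x)
}

#' Time of the last constant-stress segment end
#'
#' The post-stress (withdrawal) period of a scenario starts when the
#' constant elevated-input phase ends; for a decaying-input protocol this
#' is the start of the decay.
#'
#' @param protocol An `hpa_protocol`.
#' @return Time in days, or `-Inf` for a constant protocol.
#' @export
protocol_stress_end <- function(protocol) {
  stopifnot(inherits(protocol, "hpa_protocol"))
  if (nrow(protocol) == 0) return(-Inf)
  ends <- ifelse(is.finite(protocol$end), protocol$end, protocol$start)
  max(ends)
}

#' Locate baseline crossings of a state variable
#'
#' Scans the sampled trajectory for sign changes of `variable - level` and
#' refines each bracketed crossing by root finding on a cubic-spline
#' interpolant of the dense output, to ~1e-6 relative time accuracy.
#'
#' @param traj An `hpa_trajectory`.
#' @param variable State variable name (must be in the layout).
#' @param level Crossing level (default 1, the baseline).
#' @param direction `"any"`, `"rising"`, or `"falling"`.
#' @param after Only report crossings after this time (days).
#' @return Numeric vector of crossing times in days (possibly empty).
#' @export
find_crossings <- function(traj, variable, level = 1,
                           direction = c("any", "rising", "falling"),
                           after = -Inf) {
  direction <- match.arg(direction)
  stopifnot(inherits(traj, "hpa_trajectory"))
  if (!variable %in% names(traj$data)) {
    stop("`", variable, "` is not in this trajectory's layout (",
         paste(setdiff(names(traj$data), "time"), collapse = ", "), ")",
         call. = FALSE)
  }
  t <- traj$data$time
  v <- traj$data[[variable]]
  s <- v - level
  # scan consecutive nonzero samples so exact-zero grid hits are not lost
  nz <- which(s != 0)
  if (length(nz) < 2) return(numeric(0))
  sf <- stats::splinefun(t, v, method = "fmm")
  out <- numeric(0)
  rising <- logical(0)
  for (k in seq_len(length(nz) - 1)) {
    i <- nz[k]; j <- nz[k + 1]
    if (s[i] * s[j] >= 0) next
    if (j == i + 1) {
      root <- stats::uniroot(function(x) sf(x) - level, c(t[i], t[j]),
                             tol = 1e-6 * max(1, abs(t[j])))$root
    } else {
      root <- t[i + 1] # the sampled point(s) between sit exactly on the level
    }
    out <- c(out, root)
    rising <- c(rising, s[i] < 0)
  }
  keep <- switch(direction, any = rep(TRUE, length(out)),
                 rising = rising, falling = !rising)
  out <- out[keep & out > after]
  sort(out)
}

#' Write / read a trajectory file
#'
#' Trajectories serialize to a plain-text file: two `#`-prefixed header
#' lines (format tag, then a JSON metadata block carrying variant,
#' parameters, protocol, and solver settings) followed by a CSV body with
#' one column per state variable. `read_trajectory()` reconstructs an
#' equivalent `hpa_trajectory`.
#'
#' @param traj An `hpa_trajectory`.
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns an `hpa_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "hpa_trajectory"))
  segs <- as.data.frame(traj$protocol)
  if (nrow(segs) > 0) segs$end[!is.finite(segs$end)] <- NA_real_ # JSON has no Inf
  meta <- list(
    format = "hpa-trajectory", version = 1L,
    variant = traj$variant,
    params = unclass(traj$params), params_unit = "min",
    protocol = list(baseline = attr(traj$protocol, "baseline"),
                    segments = segs),
    crh_tests = lapply(traj$crh_tests, unclass),
    solver = traj$solver, time_unit = "day"
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# hpa-trajectory v1",
               paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                             digits = NA, na = "null",
                                             null = "null"))),
             con)
  utils::write.csv(as.data.frame(traj$data), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 2)
  if (length(lines) < 2 || !startsWith(lines[1], "# hpa-trajectory")) {
    stop("parse error at line 1 of ", path,
         ": missing `# hpa-trajectory` format tag", call. = FALSE)
  }
  meta <- tryCatch(
    jsonlite::fromJSON(sub("^# ", "", lines[2])),
    error = function(e) {
      stop("parse error at line 2 of ", path,
           ": invalid JSON metadata header (", conditionMessage(e), ")",
           call. = FALSE)
    }
  )
  data <- tibble::as_tibble(utils::read.csv(path, skip = 2,
                                            check.names = FALSE))
  layout <- variant_layout(meta$variant)
  if (!identical(names(data), c("time", layout))) {
    stop("parse error in ", path, " body: expected columns time, ",
         paste(layout, collapse = ", "), call. = FALSE)
  }
  pm <- meta$params
  params <- hpa_params(w1 = pm$w1, w2 = pm$w2, w3 = pm$w3,
                       wC = pm$wC, wA = pm$wA, K_GR = pm$K_GR, n = pm$n,
                       wCRHE = pm$wCRHE, W = pm$W, D = pm$D,
                       wR = pm$wR, wCR = pm$wCR, lam = pm$lam,
                       hormone_rate_unit = "min", mass_rate_unit = "min")
  segs <- meta$protocol$segments
  if (is.null(segs) || length(segs) == 0 ||
      (is.data.frame(segs) && nrow(segs) == 0)) {
    protocol <- protocol_constant(meta$protocol$baseline)
  } else {
    segs <- as.data.frame(segs)
    segs$end[is.na(segs$end)] <- Inf
    protocol <- new_protocol(segs, baseline = meta$protocol$baseline)
  }
  crh_tests <- lapply(meta$crh_tests, function(s) {
    crh_spec(t_inj = s$t_inj, dose = s$dose, width = s$width,
             window = s$window)
  })
  solver <- meta$solver
  structure(
    list(data = data, variant = meta$variant, params = params,
         protocol = protocol, crh_tests = crh_tests, solver = solver,
         model = hpa_model(meta$variant, params)),
    class = "hpa_trajectory"
  )
}
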