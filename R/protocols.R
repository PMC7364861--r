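#' Input protocols u(t)
#'
#' A protocol is an ordered set of non-overlapping segments laid over a
#' baseline input level (default 1). Two segment types exist: constant
#' steps `(start, end, u)` and exponential relaxations toward the baseline
#' `(start, end, u0, half_life)`. Times are in days. Evaluation is
#' right-continuous at segment boundaries.
#'
#' `protocol_constant()` is a bare baseline; `protocol_step()` is the
#' prolonged-stress pulse (defaults: `u = 4` for 90 days, the reference
#' chronic-stress scenario); `protocol_step_decay()` holds the step and
#' then relaxes exponentially back to baseline instead of dropping — the
#' "slowly decaying input" alternative mechanism (default half-life one
#' month, matching the other slow variants).
#'
#' @param u,u0 Input level of the step / initial level of the decay.
#' @param start,end Segment limits in days (`end` may be `Inf` for a
#'   terminal decay segment).
#' @param baseline Input level outside all segments (default 1).
#' @param half_life Half-life of the exponential return, in days.
#' @param duration Length of the constant phase of `protocol_step_decay()`.
#' @return An object of class `hpa_protocol` (a tibble of segments plus a
#'   `baseline` attribute).
#' @examples
#' pr <- protocol_step(u = 4, start = 0, end = 90)
#' input_at(pr, c(-1, 30, 100))
#' @name protocols
NULL

new_protocol <- function(segments, baseline = 1) {
  stopifnot(is.data.frame(segments))
  segments <- tibble::as_tibble(segments)[, c("type", "start", "end", "u", "half_life")]
  segments$type <- as.character(segments$type)
  for (col in c("start", "end", "u", "half_life")) {
    segments[[col]] <- as.numeric(segments[[col]])
  }
  if (nrow(segments) > 0) {
    segments <- segments[order(segments$start), ]
    if (any(!is.finite(segments$start)) ||
        any(is.na(segments$end)) || any(segments$end <= segments$start)) {
      stop("segment times must be finite starts with end > start", call. = FALSE)
    }
    if (nrow(segments) > 1 &&
        any(segments$start[-1] < segments$end[-nrow(segments)])) {
      stop("protocol segments must not overlap", call. = FALSE)
    }
    if (any(segments$u < 0)) stop("input u must be non-negative", call. = FALSE)
  }
  if (!is.finite(baseline) || baseline < 0) {
    stop("baseline input must be non-negative and finite", call. = FALSE)
  }
  structure(segments, baseline = baseline,
            class = c("hpa_protocol", class(segments)))
}

#' @rdname protocols
#' @export
protocol_constant <- function(u = 1) {
  new_protocol(tibble::tibble(type = character(), start = numeric(),
                              end = numeric(), u = numeric(),
                              half_life = numeric()),
               baseline = u)
}

#' @rdname protocols
#' @export
protocol_step <- function(u = 4, start = 0, end = 90, baseline = 1) {
  new_protocol(tibble::tibble(type = "step", start = start, end = end,
                              u = u, half_life = NA_real_),
               baseline = baseline)
}

#' @rdname protocols
#' @export
protocol_step_decay <- function(u = 4, start = 0, duration = 90,
                                half_life = 30, baseline = 1) {
  if (!is.finite(half_life) || half_life <= 0) {
    stop("`half_life` must be positive", call. = FALSE)
  }
  t_switch <- start + duration
  new_protocol(
    tibble::tibble(type = c("step", "exp"),
                   start = c(start, t_switch),
                   end = c(t_switch, Inf),
                   u = u, half_life = c(NA_real_, half_life)),
    baseline = baseline
  )
}

#' Evaluate an input protocol
#'
#' @param protocol An `hpa_protocol`.
#' @param t Times in days (vectorized). Evaluation is right-continuous:
#'   at a segment's start the segment value applies; at its end the
#'   following value applies.
#' @return Numeric vector of input levels.
#' @export
input_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "hpa_protocol"))
  if (any(!is.finite(t))) stop("`t` must be finite", call. = FALSE)
  base <- attr(protocol, "baseline")
  out <- rep(base, length(t))
  for (i in seq_len(nrow(protocol))) {
    seg <- protocol[i, ]
    inside <- t >= seg$start & t < seg$end
    if (!any(inside)) next
    if (seg$type == "step") {
      out[inside] <- seg$u
    } else {
      out[inside] <- base + (seg$u - base) *
        2^(-(t[inside] - seg$start) / seg$half_life)
    }
  }
  out
}

#' @export
print.hpa_protocol <- function(x, ...) {
  cat("<hpa_protocol> baseline u =", attr(x, "baseline"), "\n")
  if (nrow(x) == 0) {
    cat("  (no segments)\n")
  } else {
    print(tibble::as_tibble(x))
  }
  invisible(x)
}

#' CRH stimulation-test dosing specification
#'
#' The clinical CRH test is modelled as a boxcar infusion of exogenous CRH:
#' dose `D` on the half-open interval \eqn{(T_{inj}, T_{inj} + W]}, zero
#' elsewhere, cleared at rate `wCRHE`. Defaults are the calibrated values
#' `D = 20`, `W = 30` min, which reproduce mean test responses of
#' non-stressed controls.
#'
#' @param t_inj Injection time in days (on the trajectory's clock).
#' @param dose Dimensionless dose `D`.
#' @param width Bolus width `W` in minutes.
#' @param window Observation window in minutes (default 180; must be
#'   at least `width`).
#' @param params Optional [hpa_params()] supplying the defaults for
#'   `dose` and `width`.
#' @return An object of class `hpa_crh_spec`.
#' @examples
#' crh_spec(t_inj = 100)
#' @export
crh_spec <- function(t_inj = 0, dose = NULL, width = NULL, window = 180,
                     params = hpa_params()) {
  dose <- dose %||% params$D
  width <- width %||% params$W
  if (!is.finite(dose) || dose < 0) stop("`dose` must be non-negative", call. = FALSE)
  if (!is.finite(width) || width <= 0) stop("`width` must be positive", call. = FALSE)
  if (!is.finite(window) || window < width) {
    stop("`window` must be at least the bolus `width`", call. = FALSE)
  }
  structure(list(t_inj = t_inj, dose = dose, width = width, window = window),
            class = "hpa_crh_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the CRH-test boxcar dose
#'
#' @param spec An [crh_spec()] object.
#' @param t_min Times in minutes past the injection-day origin (i.e. on the
#'   same minute clock used internally; `t_inj` is converted to minutes).
#' @return `dose` on \eqn{(T_{inj}, T_{inj}+W]}, else 0. Vectorized.
#' @export
crh_dose_at <- function(spec, t_min) {
  stopifnot(inherits(spec, "hpa_crh_spec"))
  if (any(!is.finite(t_min))) stop("`t_min` must be finite", call. = FALSE)
  t0 <- spec$t_inj * 1440
  ifelse(t_min > t0 & t_min <= t0 + spec$width, spec$dose, 0)
}
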