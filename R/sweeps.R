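#' Sweep the GR feedback strength over the prolonged-stress scenario
#'
#' Runs the full gland-mass model through the same stress protocol for a
#' grid of `K_GR` values and summarizes the dysregulation: the peak
#' adrenal mass reached during the stressor and the largest post-stress
#' cortisol deviation from baseline. Weaker GR feedback (larger `K_GR`)
#' lets the adrenal grow more during stress and produces a larger
#' dysregulation afterwards — strong GR feedback is protective.
#'
#' @param K_GR_values Numeric vector of halfway-effect constants
#'   (default `c(2, 4, 8)`: strong, moderate, weak feedback).
#' @param protocol Stress protocol (default: the 90-day `u = 4` pulse).
#' @param t_end Span in days.
#' @param params Baseline parameter set; `K_GR` is overridden per run.
#' @param rtol,atol,hmax,grid_hours Solver settings.
#' @return Tibble with one row per `K_GR`: `peak_A_stress` (max adrenal
#'   mass while the stressor is on) and `max_x3_dev_post` (max
#'   `|cortisol - 1|` after stress end).
#' @export
sweep_kgr <- function(K_GR_values = c(2, 4, 8), protocol = protocol_step(),
                      t_end = 300, params = hpa_params(),
                      rtol = 1e-8, atol = 1e-10, hmax = 10,
                      grid_hours = 1) {
  stress_end <- protocol_stress_end(protocol)
  purrr::map_dfr(K_GR_values, function(k) {
    p <- params
    p$K_GR <- k
    traj <- simulate_hpa(hpa_model("full_mass", p), protocol,
                         t_end = t_end, rtol = rtol, atol = atol,
                         hmax = hmax, grid_hours = grid_hours)
    d <- traj$data
    during <- d$time <= stress_end
    post <- d$time > stress_end
    tibble::tibble(K_GR = k,
                   peak_A_stress = max(d$A[during]),
                   max_x3_dev_post = max(abs(d$x3[post] - 1)))
  })
}

#' Dysregulation summary across model variants
#'
#' Runs each variant through the same prolonged-stress scenario, builds
#' its CRH-test response timeline, classifies withdrawal phases, and
#' reports whether an intermediate-withdrawal (IW) window — normal
#' cortisol response with blunted ACTH response — exists. Only the
#' gland-mass model produces one; the constant-mass alternatives
#' (GR resistance, slow clearance, slowly decaying input) do not, because
#' their slow processes never break the coupling between ACTH and
#' cortisol.
#'
#' The `slow_input` variant automatically replaces the abrupt stress end
#' with an exponential relaxation of matching one-month half-life.
#'
#' @param variants Character vector of variant ids.
#' @param protocol Step protocol defining the stress pulse.
#' @param test_days CRH-test schedule in days (default: every 2 days).
#' @param t_end Span in days.
#' @param normal_band,blunt_threshold Passed to [classify_phases()].
#' @param decay_half_life Half-life (days) of the input decay used by
#'   `slow_input`.
#' @param params,rtol,atol,hmax Model and solver settings.
#' @return Tibble with columns `variant`, `iw_present`, `iw_duration`
#'   (days), `min_acth_ratio`, `min_cortisol_ratio`.
#' @export
dysregulation_summary <- function(variants = c("full_mass", "gr_resistance",
                                               "slow_clearance", "slow_input"),
                                  protocol = protocol_step(),
                                  test_days = NULL, t_end = 300,
                                  normal_band = 0.05, blunt_threshold = 0.9,
                                  decay_half_life = 30,
                                  params = hpa_params(),
                                  rtol = 1e-8, atol = 1e-10, hmax = 10) {
  if (is.null(test_days)) test_days <- seq(0, t_end, by = 2)
  purrr::map_dfr(variants, function(v) {
    pr <- protocol
    if (v == "slow_input") {
      step <- protocol[protocol$type == "step", ]
      if (nrow(step) == 0) stop("`slow_input` needs a step protocol to relax",
                                call. = FALSE)
      pr <- protocol_step_decay(u = step$u[1], start = step$start[1],
                                duration = step$end[1] - step$start[1],
                                half_life = decay_half_life,
                                baseline = attr(protocol, "baseline"))
    }
    tl <- response_timeline(v, pr, test_days = test_days, t_end = t_end,
                            params = params, rtol = rtol, atol = atol,
                            hmax = hmax)
    ph <- classify_phases(tl, normal_band, blunt_threshold)
    post <- tl$day > attr(tl, "stress_end")
    tibble::tibble(variant = v,
                   iw_present = phase_duration(ph, "IW") > 0 ||
                     any(ph$labels$phase == "IW"),
                   iw_duration = phase_duration(ph, "IW"),
                   min_acth_ratio = min(tl$acth_ratio[post]),
                   min_cortisol_ratio = min(tl$cortisol_ratio[post]))
  })
}
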