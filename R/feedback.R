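#' Cortisol feedback through the mineralocorticoid receptor (MR)
#'
#' The high-affinity MR is saturated at physiological cortisol, so its
#' effect is the Michaelis-Menten function in the saturated regime,
#' \eqn{M(x_3) = 1/x_3} (the Michaelis constant is absorbed into the
#' production terms of the non-dimensionalized circuit).
#'
#' @param x3 Cortisol level(s), dimensionless (baseline 1). Must be > 0.
#' @return `1/x3`.
#' @examples
#' feedback_mr(c(1, 2)) # 1, 0.5
#' @export
feedback_mr <- function(x3) {
  if (any(!is.finite(x3)) || any(x3 <= 0)) {
    stop("`x3` (cortisol) must be strictly positive for MR feedback 1/x3",
         call. = FALSE)
  }
  1 / x3
}

#' Cortisol feedback through the glucocorticoid receptor (GR)
#'
#' The low-affinity, cooperative GR is modelled as a decreasing Hill
#' function \eqn{G(x_3) = 1 / (1 + (R x_3 / K_{GR})^n)}. The resistance
#' factor `R` (baseline 1 in the reference model) rescales the effective
#' binding of cortisol; `R < 1` means weaker feedback.
#'
#' @inheritParams feedback_mr
#' @param K_GR Halfway-effect constant (default 4).
#' @param n Hill exponent (default 3).
#' @param R Resistance factor (default 1).
#' @return `G(x3)` in (0, 1].
#' @examples
#' feedback_gr(4, K_GR = 4) # 0.5 by definition of the halfway constant
#' @export
feedback_gr <- function(x3, K_GR = 4, n = 3, R = 1) {
  if (any(!is.finite(x3)) || any(x3 < 0)) {
    stop("`x3` (cortisol) must be non-negative for GR feedback", call. = FALSE)
  }
  if (any(R < 0)) stop("`R` (resistance factor) must be non-negative", call. = FALSE)
  1 / (1 + (R * x3 / K_GR)^n)
}

#' Baseline-normalized feedback factors g1 and g2
#'
#' The CRH production term carries both receptors, \eqn{g_1 = M \cdot G},
#' and the ACTH production term carries the GR alone, \eqn{g_2 = G}. Both
#' are divided by their value at the basal state \eqn{x_3 = 1} (with
#' `R = 1`), so that `g1(1) = g2(1) = 1` and the all-ones state is an exact
#' fixed point of the non-dimensionalized circuit.
#'
#' @inheritParams feedback_mr
#' @param params An [hpa_params()] object supplying `K_GR` and `n`.
#' @param R Resistance factor entering `G` (default 1); the normalizing
#'   constant is always evaluated at `R = 1`.
#' @return A tibble with columns `x3`, `g1`, `g2`.
#' @examples
#' feedback_terms(c(1, 2), hpa_params())
#' @export
feedback_terms <- function(x3, params = hpa_params(), R = 1) {
  if (any(!is.finite(x3)) || any(x3 <= 0)) {
    stop("`x3` (cortisol) must be strictly positive", call. = FALSE)
  }
  gnorm <- feedback_gr(1, params$K_GR, params$n, R = 1)
  g2 <- feedback_gr(x3, params$K_GR, params$n, R = R) / gnorm
  tibble::tibble(x3 = x3, g1 = g2 / x3, g2 = g2)
}
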