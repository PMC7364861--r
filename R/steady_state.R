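#' Steady state of the gland-mass circuit at constant input
#'
#' The mass equations act as integral feedback: their only fixed point pins
#' CRH and ACTH at baseline (`x1 = x2 = 1`) regardless of `u` — exact
#' adaptation. Cortisol then solves the scalar equation
#' \eqn{x_3 = u\,G(x_3)/G(1)} (found by root bracketing and refinement),
#' the adrenal mass is `A = x3`, and the corticotroph mass is
#' `C = 1/g2(x3) = u/x3`.
#'
#' @param params An [hpa_params()] object.
#' @param u Constant input level, > 0.
#' @param tol Absolute tolerance for the cortisol root (default 1e-12).
#' @return A one-row tibble with columns `u`, `x1`, `x2`, `x3`, `C`, `A`,
#'   and `residual` (the max-norm of the full right-hand side at the
#'   returned state, per minute).
#' @examples
#' steady_state(hpa_params(), u = 1) # the all-ones state
#' steady_state(hpa_params(), u = 4)
#' @export
steady_state <- function(params = hpa_params(), u = 1, tol = 1e-12) {
  if (!is.finite(u) || u <= 0) stop("`u` must be strictly positive", call. = FALSE)
  gnorm <- feedback_gr(1, params$K_GR, params$n)
  f <- function(x3) x3 - u * feedback_gr(x3, params$K_GR, params$n) / gnorm
  lo <- 1e-6
  hi <- max(10, 10 * u)
  if (f(lo) >= 0 || f(hi) <= 0) {
    stop(sprintf(paste0("cortisol root not bracketed in [%g, %g] ",
                        "(f(lo)=%g, f(hi)=%g) at u=%g"),
                 lo, hi, f(lo), f(hi), u), call. = FALSE)
  }
  x3 <- stats::uniroot(f, c(lo, hi), tol = tol)$root
  st <- c(x1 = 1, x2 = 1, x3 = x3, C = u / x3, A = x3, x1E = 0)
  res <- max(abs(hpa_rhs(hpa_model("full_mass", params), st, u = u)))
  tibble::tibble(u = u, x1 = 1, x2 = 1, x3 = x3, C = u / x3, A = x3,
                 residual = res)
}

#' Quasi-steady state of the fast hormone subsystem
#'
#' With gland masses `C`, `A` frozen, the hormones equilibrate within hours.
#' Mode `"approx"` returns the closed forms obtained by neglecting the
#' deviation of GR feedback from its baseline value:
#' \eqn{x_3 = \sqrt{A C u}}, \eqn{x_1 = u/x_3}, \eqn{x_2 = x_3/A}
#' (reducing to the printed square-root forms at `u = 1`). Mode `"exact"`
#' solves the fast fixed point \eqn{x_3 G(1) = \sqrt{ACu}\, G(x_3)} by root
#' finding. The two agree closely while \eqn{x_3 \ll K_{GR}}.
#'
#' @param C,A Gland functional masses, > 0.
#' @param u Input level, > 0.
#' @param params An [hpa_params()] object.
#' @param mode `"approx"` (closed form) or `"exact"` (root finding).
#' @return A one-row tibble with columns `x1`, `x2`, `x3`.
#' @examples
#' fast_qss(C = 4, A = 1) # x2 = 2, x3 = 2, x1 = 0.5
#' @export
fast_qss <- function(C, A, u = 1, params = hpa_params(),
                     mode = c("approx", "exact")) {
  mode <- match.arg(mode)
  if (any(!is.finite(c(C, A, u))) || any(c(C, A, u) <= 0)) {
    stop("`C`, `A`, and `u` must be strictly positive", call. = FALSE)
  }
  s <- sqrt(A * C * u)
  if (mode == "approx") {
    x3 <- s
    x1 <- u / x3
  } else {
    gnorm <- feedback_gr(1, params$K_GR, params$n)
    f <- function(x3) x3 * gnorm - s * feedback_gr(x3, params$K_GR, params$n)
    x3 <- stats::uniroot(f, c(1e-8, max(10, 10 * s)), tol = 1e-12)$root
    x1 <- u * feedback_terms(x3, params)$g1
  }
  tibble::tibble(x1 = x1, x2 = x3 / A, x3 = x3)
}
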