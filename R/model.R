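VARIANTS <- c("full_mass", "classic", "gr_resistance", "slow_clearance",
              "slow_input")

# integer codes understood by the compiled core; slow_input shares the
# classic right-hand side and differs only in its input protocol
variant_code <- function(variant) {
  switch(variant,
    full_mass = 0L, classic = 1L, gr_resistance = 2L,
    slow_clearance = 3L, slow_input = 1L,
    stop("unknown variant `", variant, "`; valid ids: ",
         paste(VARIANTS, collapse = ", "), call. = FALSE)
  )
}

variant_layout <- function(variant) {
  switch(variant,
    full_mass = c("x1", "x2", "x3", "C", "A", "x1E"),
    classic = ,
    slow_input = c("x1", "x2", "x3", "x1E"),
    gr_resistance = c("x1", "x2", "x3", "x1E", "R"),
    slow_clearance = c("x1", "x2", "x3", "x1E", "CR"),
    stop("unknown variant `", variant, "`; valid ids: ",
         paste(VARIANTS, collapse = ", "), call. = FALSE)
  )
}

#' Construct a model definition for one circuit variant
#'
#' Five variants share a common interface: the reference model with gland
#' functional-mass dynamics (`"full_mass"`), the classic constant-mass
#' cascade (`"classic"`), and three constant-mass alternatives carrying a
#' slow process of about a month — glucocorticoid-receptor resistance
#' (`"gr_resistance"`), a slow cortisol-clearance modifier
#' (`"slow_clearance"`), and a slowly decaying input signal
#' (`"slow_input"`, the classic equations paired with an exponential
#' protocol).
#'
#' Each definition records its state layout and a baseline state that is an
#' exact fixed point of its equations at basal input `u = 1`. For
#' `gr_resistance` the basal resistance is \eqn{R^* = 1/(1+\lambda)} (the
#' steady state of the resistance equation at basal cortisol) and the
#' feedback normalization constant is frozen at \eqn{G(1, R^*)} so the
#' all-ones hormone state stays an exact fixed point while transient
#' departures of `R` genuinely shift feedback strength.
#'
#' @param variant One of `"full_mass"`, `"classic"`, `"gr_resistance"`,
#'   `"slow_clearance"`, `"slow_input"`.
#' @param params An [hpa_params()] object.
#' @return An object of class `hpa_model` with elements `variant`, `layout`,
#'   `baseline` (named state vector), `params`, and the internal
#'   normalization constant.
#' @examples
#' m <- hpa_model("full_mass")
#' m$baseline
#' @export
hpa_model <- function(variant = "full_mass", params = hpa_params()) {
  variant <- match.arg(variant, VARIANTS)
  layout <- variant_layout(variant)
  R_base <- if (variant == "gr_resistance") 1 / (1 + params$lam) else 1
  gnorm <- feedback_gr(1, params$K_GR, params$n, R = R_base)
  baseline <- stats::setNames(rep(1, length(layout)), layout)
  baseline["x1E"] <- 0
  if (variant == "gr_resistance") baseline["R"] <- R_base
  structure(
    list(variant = variant, layout = layout, baseline = baseline,
         params = params, gnorm = gnorm, R_base = R_base),
    class = "hpa_model"
  )
}

#' @export
print.hpa_model <- function(x, ...) {
  cat("<hpa_model>", x$variant, "\n")
  cat("  state:", paste(x$layout, collapse = ", "), "\n")
  cat("  baseline:", paste(sprintf("%s=%g", x$layout, x$baseline),
                           collapse = " "), "\n")
  invisible(x)
}

# parameter list handed to the compiled core (per-minute rates + gnorm)
cpp_pars <- function(model) {
  p <- model$params
  list(w1 = p$w1, w2 = p$w2, w3 = p$w3, wC = p$wC, wA = p$wA,
       K_GR = p$K_GR, n = p$n, wCRHE = p$wCRHE, wR = p$wR, wCR = p$wCR,
       lam = p$lam, gnorm = model$gnorm)
}

#' Evaluate a model's right-hand side
#'
#' Time derivatives of the state, in per-minute units, at a given input
#' level and (constant) exogenous-CRH dose. This is the single compiled
#' definition also used by the integrator.
#'
#' @param model An [hpa_model()] object.
#' @param state Named or unnamed numeric state vector matching the model's
#'   layout.
#' @param u Input (stress) level, non-negative.
#' @param crh_dose Exogenous CRH dose currently being infused (default 0).
#' @param t Time in minutes (the autonomous equations ignore it; kept for
#'   interface symmetry).
#' @return Named numeric vector of derivatives (per minute).
#' @examples
#' m <- hpa_model("full_mass")
#' hpa_rhs(m, m$baseline, u = 1) # all zeros: exact fixed point
#' @export
hpa_rhs <- function(model, state, u, crh_dose = 0, t = 0) {
  stopifnot(inherits(model, "hpa_model"))
  if (!is.numeric(state) || length(state) != length(model$layout)) {
    stop("`state` must be numeric of length ", length(model$layout),
         " (", paste(model$layout, collapse = ", "), ")", call. = FALSE)
  }
  if (!is.null(names(state))) state <- state[model$layout]
  if (any(!is.finite(state))) stop("non-finite state component", call. = FALSE)
  if (state[3] <= 0) stop("`x3` (cortisol) must be strictly positive", call. = FALSE)
  if (!is.finite(u) || u < 0) stop("input `u` must be non-negative", call. = FALSE)
  dy <- hpa_rhs_eval(variant_code(model$variant), t, as.numeric(state),
                     cpp_pars(model), u, crh_dose)
  stats::setNames(dy, model$layout)
}
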