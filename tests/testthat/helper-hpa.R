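# Independent pure-R evaluation of the circuit equations, written directly
# from the model definitions (not via the package's compiled core). Used as
# the oracle for RHS equivalence and fixed-point checks.
ref_rhs <- function(variant, state, params, u, dose = 0) {
  p <- params
  x1 <- state[["x1"]]; x2 <- state[["x2"]]; x3 <- state[["x3"]]
  C <- if ("C" %in% names(state)) state[["C"]] else 1
  A <- if ("A" %in% names(state)) state[["A"]] else 1
  R <- if ("R" %in% names(state)) state[["R"]] else 1
  CR <- if ("CR" %in% names(state)) state[["CR"]] else 1
  x1E <- state[["x1E"]]
  R_base <- if (variant == "gr_resistance") 1 / (1 + p$lam) else 1
  G <- function(x, r) 1 / (1 + (r * x / p$K_GR)^p$n)
  gnorm <- G(1, R_base)
  g2 <- G(x3, R) / gnorm
  g1 <- (1 / x3) * G(x3, R) / gnorm
  d <- c(
    x1 = p$w1 * (u * g1 - x1),
    x2 = p$w2 * (C * g2 * (x1 + x1E) - x2),
    x3 = p$w3 * (A * x2 - if (variant == "slow_clearance") x3 / CR else x3)
  )
  if (variant == "full_mass") {
    d <- c(d, C = p$wC * C * (x1 - 1), A = p$wA * A * (x2 - 1))
  }
  d <- c(d, x1E = p$wCRHE * (dose - x1E))
  if (variant == "gr_resistance") {
    d <- c(d, R = p$wR * (1 - (1 + p$lam * x3^2) * R))
  }
  if (variant == "slow_clearance") {
    d <- c(d, CR = p$wCR * (x3 - CR))
  }
  d[names(state)]
}

# random strictly positive state for a variant's layout (x1E in [0, 2))
random_state <- function(model) {
  st <- stats::setNames(stats::runif(length(model$layout), 0.3, 3),
                        model$layout)
  st["x1E"] <- stats::runif(1, 0, 2)
  if ("R" %in% names(st)) st["R"] <- stats::runif(1, 0.1, 1)
  st
}

# the reference chronic-stress scenario: u = 4 for 90 days, then basal
stress_protocol <- function() protocol_step(u = 4, start = 0, end = 90)
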