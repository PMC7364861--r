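#' Model parameters for the HPA gland-mass circuit
#'
#' Builds the validated parameter record used by every model variant. The
#' defaults are the published reference set for the non-dimensionalized
#' hypothalamic-pituitary-adrenal (HPA) circuit: hormone removal rates are
#' given per minute, gland-mass and slow-process turnover rates per day.
#' Internally every rate is converted to a single canonical time unit
#' (minutes), recorded in the object's `unit` attribute.
#'
#' @param w1 CRH removal rate (default 0.17; half-life ~ 4 min).
#' @param w2 ACTH removal rate (default 0.035; half-life ~ 20 min).
#' @param w3 Cortisol removal rate (default 0.0086; half-life ~ 80 min).
#' @param wC Corticotroph functional-mass turnover rate (default 0.099).
#' @param wA Adrenal-cortex functional-mass turnover rate (default 0.049).
#' @param K_GR Glucocorticoid-receptor (GR) halfway-effect constant, in
#'   dimensionless cortisol units (default 4). Must exceed 1.
#' @param n GR Hill exponent (default 3), a positive integer.
#' @param wCRHE Removal rate of exogenously injected CRH (default 0.016).
#' @param W CRH-test bolus width in minutes (default 30).
#' @param D CRH-test bolus dose, dimensionless CRH units (default 20).
#' @param wR Relaxation rate of the GR-resistance variable (default log(2)/30,
#'   i.e. a one-month half-life).
#' @param wCR Relaxation rate of the cortisol-clearance modifier (default
#'   log(2)/30).
#' @param lam Resistance-response coefficient \eqn{\lambda} (default 1).
#' @param hormone_rate_unit Unit of `w1`, `w2`, `w3`, `wCRHE` as supplied:
#'   `"min"` (default) or `"day"`.
#' @param mass_rate_unit Unit of `wC`, `wA`, `wR`, `wCR` as supplied:
#'   `"day"` (default) or `"min"`.
#'
#' @return An object of class `hpa_params`: a named list of rates in
#'   per-minute units plus the dimensionless constants.
#' @examples
#' p <- hpa_params()
#' log(2) / p$w2 # ACTH half-life in minutes
#' @export
hpa_params <- function(w1 = 0.17, w2 = 0.035, w3 = 0.0086,
                       wC = 0.099, wA = 0.049,
                       K_GR = 4, n = 3,
                       wCRHE = 0.016, W = 30, D = 20,
                       wR = log(2) / 30, wCR = log(2) / 30, lam = 1,
                       hormone_rate_unit = c("min", "day"),
                       mass_rate_unit = c("day", "min")) {
  hormone_rate_unit <- match.arg(hormone_rate_unit)
  mass_rate_unit <- match.arg(mass_rate_unit)
  hconv <- if (hormone_rate_unit == "day") 1 / 1440 else 1
  mconv <- if (mass_rate_unit == "day") 1 / 1440 else 1

  p <- list(
    w1 = w1 * hconv, w2 = w2 * hconv, w3 = w3 * hconv,
    wC = wC * mconv, wA = wA * mconv,
    K_GR = K_GR, n = n,
    wCRHE = wCRHE * hconv, W = W, D = D,
    wR = wR * mconv, wCR = wCR * mconv, lam = lam
  )
  rates <- c("w1", "w2", "w3", "wC", "wA", "wCRHE", "wR", "wCR")
  bad <- rates[vapply(p[rates], function(x) !is.finite(x) || x <= 0, logical(1))]
  if (length(bad) > 0) {
    stop("rate parameter(s) must be strictly positive and finite: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.finite(n) || n <= 0 || n != round(n)) {
    stop("Hill exponent `n` must be a positive integer", call. = FALSE)
  }
  if (!is.finite(K_GR) || K_GR <= 1) {
    stop("`K_GR` must exceed 1 (low-affinity receptor regime)", call. = FALSE)
  }
  if (!is.finite(W) || W <= 0 || !is.finite(D) || D < 0) {
    stop("CRH-test dose `D` must be non-negative and width `W` positive",
         call. = FALSE)
  }
  if (!is.finite(lam) || lam < 0) stop("`lam` must be non-negative", call. = FALSE)
  structure(p, class = "hpa_params", unit = "min")
}

#' Read a parameter set from a JSON configuration file
#'
#' The file is keyed by the published symbol names (`w1`, `w2`, `w3`, `wC`,
#' `wA`, `K_GR`, `n`, `wCRHE`, `W`, `D`, `wR`, `wCR`, `lam`); missing keys fall
#' back to the packaged defaults. The legacy aliases `wCE` (for `wCR`) and
#' `lambda` (for `lam`) are accepted. Rates must be given in the reference
#' units (hormones per minute, masses per day).
#'
#' @param path Path to a JSON file.
#' @return An [hpa_params()] object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$wCE) && is.null(raw$wCR)) raw$wCR <- raw$wCE
  if (!is.null(raw$lambda) && is.null(raw$lam)) raw$lam <- raw$lambda
  keys <- c("w1", "w2", "w3", "wC", "wA", "K_GR", "n", "wCRHE",
            "W", "D", "wR", "wCR", "lam")
  unknown <- setdiff(names(raw), c(keys, "wCE", "lambda", "comment"))
  if (length(unknown) > 0) {
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(hpa_params, raw[intersect(keys, names(raw))])
}

#' @export
print.hpa_params <- function(x, ...) {
  cat("<hpa_params> (canonical unit: per", attr(x, "unit"), "for rates)\n")
  cat(sprintf("  hormones : w1=%g w2=%g w3=%g /min\n", x$w1, x$w2, x$w3))
  cat(sprintf("  masses   : wC=%g wA=%g /day\n", x$wC * 1440, x$wA * 1440))
  cat(sprintf("  feedback : K_GR=%g n=%d\n", x$K_GR, as.integer(x$n)))
  cat(sprintf("  CRH test : D=%g W=%g min, wCRHE=%g /min\n", x$D, x$W, x$wCRHE))
  cat(sprintf("  slow alt : wR=%g wCR=%g /day, lambda=%g\n",
              x$wR * 1440, x$wCR * 1440, x$lam))
  invisible(x)
}
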