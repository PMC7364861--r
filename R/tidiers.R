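#' Tidy a trajectory into long format
#'
#' @param x An `hpa_trajectory`.
#' @param ... Unused.
#' @return Tibble with columns `time` (days), `variable`, `value`.
#' @export
tidy.hpa_trajectory <- function(x, ...) {
  tidyr::pivot_longer(x$data, -"time", names_to = "variable",
                      values_to = "value")
}

#' One-row summary of a trajectory
#'
#' @param x An `hpa_trajectory`.
#' @param ... Unused.
#' @return Tibble with the span, sample count, solver steps, and the
#'   final hormone and mass values.
#' @export
glance.hpa_trajectory <- function(x, ...) {
  last <- x$data[nrow(x$data), ]
  tibble::tibble(
    variant = x$variant,
    t_start = min(x$data$time), t_end = max(x$data$time),
    n_samples = nrow(x$data), n_steps = x$solver$nsteps,
    x1_end = last$x1, x2_end = last$x2, x3_end = last$x3,
    C_end = if ("C" %in% names(last)) last$C else 1,
    A_end = if ("A" %in% names(last)) last$A else 1
  )
}

#' @export
tidy.hpa_timeline <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x)[c("day", "acth_ratio", "cortisol_ratio")],
                      -"day", names_to = "hormone", values_to = "ratio",
                      names_pattern = "(.*)_ratio")
}

#' @export
glance.hpa_timeline <- function(x, ...) {
  post <- x$day > attr(x, "stress_end")
  tibble::tibble(
    variant = attr(x, "variant"),
    n_tests = nrow(x),
    stress_end = attr(x, "stress_end"),
    min_acth_ratio = min(x$acth_ratio),
    min_cortisol_ratio = min(x$cortisol_ratio),
    min_acth_ratio_post = if (any(post)) min(x$acth_ratio[post]) else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
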