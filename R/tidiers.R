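# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mediation fit
#'
#' One row per path (a, b, c, c_prime, indirect) with estimates, standard
#' errors where defined, and the bias-corrected bootstrap intervals on the
#' direct (c_prime) and indirect rows.
#'
#' @param x A `netmed_mediation` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.netmed_mediation <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "c", "c_prime", "indirect"),
    estimate = c(x$a, x$b, x$c, x$c_prime, x$indirect),
    std.error = c(x$se_a, x$se_b, x$se_c, x$se_c_prime, stats::sd(x$boot_indirects)),
    conf.low = c(NA, NA, NA, x$ci_direct_low, x$ci_low),
    conf.high = c(NA, NA, NA, x$ci_direct_high, x$ci_high)
  )
}

#' One-row summary of a mediation fit
#'
#' @param x A `netmed_mediation` object.
#' @param ... Unused.
#' @return A one-row tibble with the model labels, sample size, indirect
#'   effect, interval and significance flag.
#' @export
glance.netmed_mediation <- function(x, ...) {
  obj <- x
  tibble::tibble(
    x = obj$x, m = obj$m, y = obj$y, n = obj$n,
    indirect = obj$indirect, ci_low = obj$ci_low, ci_high = obj$ci_high,
    significant = obj$significant,
    direct_significant = obj$direct_significant, n_boot = obj$n_boot,
    standardized = obj$standardized, n_redrawn = obj$n_redrawn
  )
}

#' Tidy a permutation-null result
#'
#' @param x A `netmed_perm` object.
#' @param ... Unused.
#' @return A one-row tibble with the observed coefficient, empirical
#'   p-value and null-distribution summaries.
#' @export
tidy.netmed_perm <- function(x, ...) {
  tibble::tibble(
    observed_rho = x$observed_rho,
    empirical_p = x$empirical_p,
    B = x$B,
    null_mean = mean(x$null_rhos),
    null_sd = stats::sd(x$null_rhos)
  )
}
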