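#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Mann-Whitney U test
#'
#' @param x An `immunosig_mwu` object.
#' @param ... Unused.
#' @return A one-row tibble with `u_statistic`, `p_value`, `n_a`, `n_b`,
#'   `method`.
#' @method tidy immunosig_mwu
#' @export
tidy.immunosig_mwu <- function(x, ...) {
  tibble::tibble(
    u_statistic = x$u_statistic, p_value = x$p_two_sided,
    n_a = x$n_a, n_b = x$n_b, method = x$method
  )
}

#' @export
print.immunosig_mwu <- function(x, ...) {
  cat("Mann-Whitney U test (", x$method, ")\n", sep = "")
  cat("  U = ", format(x$u_statistic), ", n = ", x$n_a, "/", x$n_b,
      ", two-sided p = ", format.pval(x$p_two_sided), "\n", sep = "")
  invisible(x)
}

#' Tidy a Kaplan-Meier fit
#'
#' @param x An `immunosig_km` object.
#' @param ... Unused.
#' @return The product-limit curve as a tibble (`time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`).
#' @method tidy immunosig_km
#' @export
tidy.immunosig_km <- function(x, ...) {
  x$curve
}

#' @rdname tidy.immunosig_km
#' @return `glance()` returns a one-row tibble with `n`, `n_events`,
#'   `median_survival`.
#' @method glance immunosig_km
#' @export
glance.immunosig_km <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events, median_survival = km_median(x)
  )
}

#' @export
print.immunosig_km <- function(x, ...) {
  cat("Kaplan-Meier fit: n = ", x$n, ", events = ", x$n_events,
      ", median survival = ", format(km_median(x)), "\n", sep = "")
  invisible(x)
}

#' Tidy a log-rank test
#'
#' @param x An `immunosig_logrank` object.
#' @param ... Unused.
#' @return A one-row tibble with `chi2`, `p_value`, `observed`,
#'   `expected`, `n_a`, `n_b`.
#' @method tidy immunosig_logrank
#' @export
tidy.immunosig_logrank <- function(x, ...) {
  tibble::tibble(
    chi2 = x$chi2, p_value = x$p, observed = x$observed,
    expected = x$expected, n_a = x$n_a, n_b = x$n_b
  )
}

#' @export
print.immunosig_logrank <- function(x, ...) {
  cat("Log-rank test: chi2 = ", format(x$chi2),
      " (1 df), p = ", format.pval(x$p), "\n", sep = "")
  invisible(x)
}

#' Tidy a per-signature survival analysis
#'
#' @param x An `immunosig_survfit` object from [run_survival()].
#' @param ... Unused.
#' @return `tidy()` returns the stacked KM curves (one row per signature,
#'   stratum and time); `glance()` the per-signature summary with the
#'   log-rank results.
#' @method tidy immunosig_survfit
#' @export
tidy.immunosig_survfit <- function(x, ...) {
  x$curves
}

#' @rdname tidy.immunosig_survfit
#' @method glance immunosig_survfit
#' @export
glance.immunosig_survfit <- function(x, ...) {
  x$summary
}

#' @export
print.immunosig_survfit <- function(x, ...) {
  cat("Median-split survival analysis,", nrow(x$summary), "signature(s)\n")
  print(x$summary)
  invisible(x)
}
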