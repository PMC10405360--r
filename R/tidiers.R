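#' Tidy a posterior trace
#'
#' One row per scalar parameter with posterior mean, median, sd and 95% HPD
#' interval.
#'
#' @param x An `mscoal_trace`.
#' @param mass HPD mass.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.mscoal_trace <- function(x, mass = 0.95, ...) {
  summarize_trace(x, mass = mass)
}

#' One-row summary of an MCMC run
#'
#' @param x An `mscoal_trace`.
#' @param ... Unused.
#' @return A tibble with the model, sample count, mean log-likelihood and
#'   the smallest per-parameter effective sample size.
#' @exportS3Method generics::glance
glance.mscoal_trace <- function(x, ...) {
  pars <- trace_parameters(x)
  tibble::tibble(
    model = as.character(attr(x, "model") %||% NA),
    nsamples = nrow(x),
    mean_lnL = if ("lnL" %in% names(x)) mean(x$lnL) else NA_real_,
    min_ess = min(vapply(pars, function(p) ess(x[[p]]), 0))
  )
}

#' Plot posterior densities of a trace
#'
#' Marginal posterior densities, one facet per parameter.
#'
#' @param object An `mscoal_trace`.
#' @param params Parameters to plot (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mscoal_trace <- function(object, params = NULL, ...) {
  params <- params %||% trace_parameters(object)
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, params, drop = FALSE],
    dplyr::all_of(params),
    names_to = "parameter", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80", colour = "grey20") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Plot a bias report
#'
#' Posterior means with HPD error bars against the generating truth
#' (dashed line at zero relative bias), per parameter.
#'
#' @param object A `bias_report` (or aggregated tibble from
#'   [aggregate_bias()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bias_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$parameter)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(
      y = .data$mean / .data$truth - 1,
      ymin = .data$hpd_lo / .data$truth - 1,
      ymax = .data$hpd_hi / .data$truth - 1
    )) +
    ggplot2::labs(x = NULL, y = "relative deviation from truth") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
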