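#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted samples; ties are broken by the lowest start.
#'
#' @param samples Numeric vector of posterior draws.
#' @param mass Target probability mass (default 0.95).
#' @return Named numeric vector `c(lo, hi)`.
#' @examples
#' hpd_interval(rnorm(1e4))
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  if (!length(samples)) stop_mscoal("no samples")
  if (mass <= 0 || mass >= 1) stop_mscoal("mass must lie in (0, 1)")
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lo = x[1], hi = x[n]))
  width <- x[seq(m, n)] - x[seq(1, n - m + 1)]
  i <- which.min(width) # which.min takes the first (lowest-start) tie
  c(lo = x[i], hi = x[i + m - 1])
}

#' Expected cumulative introgression proportion under the IM model
#'
#' The probability that a lineage sampled from the recipient population
#' traces its ancestry into the donor population at least once over a
#' migration band of duration `dtau`, with `M = Nm` migrants per
#' generation: `phi0 = 1 - exp(-4 M dtau / theta)`. This is the episodic
#' introgression probability that accumulates the whole period of
#' continuous gene flow.
#'
#' @param M Migration rate, migrants per generation (>= 0).
#' @param dtau Duration of gene flow in tau units (>= 0).
#' @param theta Recipient population size parameter (> 0).
#' @return phi0 in [0, 1). Vectorised over its arguments.
#' @examples
#' phi0_expected(M = 0.1, dtau = 0.01, theta = 0.01) # 0.33
#' @export
phi0_expected <- function(M, dtau, theta) {
  if (any(theta == 0)) stop_mscoal("theta must be positive")
  if (any(M < 0) || any(dtau < 0) || any(theta < 0)) {
    stop_mscoal("M, dtau and theta must be non-negative")
  }
  1 - exp(-4 * M * dtau / theta)
}

#' Posterior summary of a trace
#'
#' Per-parameter posterior means and HPD intervals, the building block of
#' the replicate-averaged summaries.
#'
#' @param trace An `mscoal_trace` (or data frame of draws).
#' @param params Columns to summarise (default: all parameter columns).
#' @param mass HPD mass (default 0.95).
#' @return A tibble with columns `parameter`, `mean`, `median`, `sd`,
#'   `hpd_lo`, `hpd_hi`.
#' @export
summarize_trace <- function(trace, params = NULL, mass = 0.95) {
  params <- params %||% trace_parameters(trace)
  purrr::map_dfr(params, function(p) {
    x <- trace[[p]]
    h <- hpd_interval(x, mass)
    tibble::tibble(parameter = p, mean = mean(x), median = stats::median(x),
                   sd = stats::sd(x), hpd_lo = h[["lo"]], hpd_hi = h[["hi"]])
  })
}

#' Score posterior estimates against the generating truth
#'
#' Relative bias of posterior means, `(estimate - truth)/truth`, and 95%
#' HPD coverage per parameter.
#'
#' @param x An `mscoal_trace` or a summary tibble from [summarize_trace()].
#' @param truth A [truth_record] or a named numeric vector of generating
#'   values (`tau_*`, `theta_*`, `phi_*`).
#' @param params Parameters to score; default: the intersection of trace
#'   parameters and truth names (an error if empty).
#' @return A tibble of class `bias_report` with columns `parameter`,
#'   `truth`, `mean`, `hpd_lo`, `hpd_hi`, `rel_bias`, `covered`.
#' @export
bias_report <- function(x, truth, params = NULL) {
  if (inherits(truth, "truth_record")) truth <- truth$params
  sm <- if (is.data.frame(x) && "parameter" %in% names(x)) x else
    summarize_trace(x)
  params <- params %||% intersect(sm$parameter, names(truth))
  if (!length(params)) {
    stop_mscoal("no parameter names shared between estimates and truth")
  }
  missing <- setdiff(params, sm$parameter)
  if (length(missing)) {
    stop_mscoal("parameter(s) absent from the estimates: ",
                paste(missing, collapse = ", "))
  }
  sm <- sm[match(params, sm$parameter), ]
  tv <- unname(truth[params])
  out <- tibble::tibble(
    parameter = params,
    truth = tv,
    mean = sm$mean,
    hpd_lo = sm$hpd_lo,
    hpd_hi = sm$hpd_hi,
    rel_bias = (sm$mean - tv) / tv,
    covered = tv >= sm$hpd_lo & tv <= sm$hpd_hi
  )
  class(out) <- c("bias_report", class(out))
  out
}

#' Aggregate bias reports over replicates
#'
#' Averages posterior means and HPD endpoints over replicate datasets (the
#' way replicate figures are drawn: points and error bars both averaged
#' over replicates), along with mean relative bias and coverage rates.
#'
#' @param reports List of `bias_report`s from replicate datasets.
#' @return A tibble with one row per parameter: `mean`, `hpd_lo`, `hpd_hi`
#'   (averaged), `rel_bias` (mean), `coverage` (proportion of replicates
#'   whose HPD covers the truth), `n_rep`.
#' @export
aggregate_bias <- function(reports) {
  dplyr::bind_rows(reports) |>
    dplyr::group_by(.data$parameter, .data$truth) |>
    dplyr::summarise(
      mean = mean(.data$mean),
      hpd_lo = mean(.data$hpd_lo),
      hpd_hi = mean(.data$hpd_hi),
      rel_bias = mean(.data$rel_bias),
      coverage = mean(.data$covered),
      n_rep = dplyr::n(),
      .groups = "drop"
    )
}

#' Calibrate relative divergence times to absolute ages
#'
#' Rescales mutation-scaled divergence times (tau, expected substitutions
#' per site) to absolute ages. In node mode the age of one anchor node is
#' fixed (e.g. a secondary calibration in Ma) and every sample is scaled by
#' `anchor_age / tau_anchor` for that sample; in rate mode ages are
#' `tau / rate` with a substitution rate per Ma. Calibration uncertainty in
#' the anchor itself is not modelled.
#'
#' @param tau_samples A trace or data frame containing `tau_*` columns.
#' @param anchor Column name of the anchor node's age (node mode).
#' @param anchor_age Absolute age of the anchor node (same time unit as the
#'   answer, e.g. Ma).
#' @param rate Substitution rate per site per time unit (rate mode;
#'   supply either `anchor_age` or `rate`, not both).
#' @return A tibble of calibrated ages with the same `tau_*` columns.
#' @export
calibrate_ages <- function(tau_samples, anchor = NULL, anchor_age = NULL,
                           rate = NULL) {
  cols <- grep("^tau_", names(tau_samples), value = TRUE)
  if (!length(cols)) stop_mscoal("no tau_* columns to calibrate")
  if (!is.null(anchor_age) && !is.null(rate)) {
    stop_mscoal("supply either anchor_age (node mode) or rate, not both")
  }
  if (!is.null(anchor_age)) {
    if (is.null(anchor) || !anchor %in% names(tau_samples)) {
      stop_mscoal("anchor column not found")
    }
    ta <- tau_samples[[anchor]]
    if (any(ta == 0)) stop_mscoal("anchor age is zero in some samples")
    scale <- anchor_age / ta
  } else if (!is.null(rate)) {
    if (rate <= 0) stop_mscoal("rate must be positive")
    scale <- 1 / rate
  } else {
    stop_mscoal("supply anchor_age or rate")
  }
  out <- tibble::as_tibble(tau_samples)[, cols]
  for (cl in cols) out[[cl]] <- out[[cl]] * scale
  out
}
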