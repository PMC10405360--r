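# Internal helpers shared across modules.

#' Derive a per-locus random seed from a base seed
#'
#' Locus `i` always receives the same substream seed regardless of how many
#' loci are simulated, so replicate datasets are reproducible locus by locus.
#'
#' @param seed Integer base seed.
#' @param i Locus index (1-based).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
locus_seed <- function(seed, i) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(i) * 69621
  as.integer(s %% 2147483646) + 1L
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logmeanexp <- function(x) logsumexp(x) - log(length(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mscoal <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
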