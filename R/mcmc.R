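#' Prior specification for MSC/MSci inference
#'
#' Population sizes get inverse-gamma(alpha, beta) priors with `beta` chosen
#' so that the prior mean `beta/(alpha - 1)` equals `theta_mean`; the root
#' age gets inverse-gamma(alpha, beta) with prior mean `tau_mean`. With
#' `alpha = 3` these are diffuse, heavy-tailed priors. Given the root age,
#' the other divergence times (hybrid times included) are uniform-Dirichlet:
#' flat over the order-constrained region, with density proportional to
#' `tau_root^-(k)` for `k` interior time parameters. Introgression
#' probabilities get Beta(1, 1), i.e. uniform on (0, 1).
#'
#' @param theta_mean Prior mean for every population's theta.
#' @param tau_mean Prior mean for the root age.
#' @param alpha Inverse-gamma shape (> 2 so the mean exists; default 3).
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(theta_mean, tau_mean, alpha = 3) {
  if (alpha <= 2) stop_mscoal("alpha must exceed 2 (finite prior mean)")
  if (theta_mean <= 0 || tau_mean <= 0) {
    stop_mscoal("prior means must be positive")
  }
  structure(list(
    alpha = alpha,
    theta_mean = theta_mean,
    beta_theta = theta_mean * (alpha - 1),
    tau_mean = tau_mean,
    beta_tau = tau_mean * (alpha - 1)
  ), class = "prior_spec")
}

#' MCMC run configuration
#'
#' Defaults follow the simulation protocol: 200,000 posterior samples after
#' a burn-in of 20,000 iterations, sampling every 2 iterations. The
#' `"empirical"` preset mirrors the heavier protocol used for real
#' datasets: 10,000 samples every 200 iterations after a 200,000-iteration
#' burn-in. Step sizes are auto-tuned toward ~30% acceptance during burn-in
#' only and frozen afterwards.
#'
#' @param burnin Burn-in sweeps.
#' @param nsamples Recorded posterior samples.
#' @param thin Record every `thin`-th sweep.
#' @param seed Integer RNG seed (drives the sampler and the gene-tree
#'   initialisation).
#' @param nexch Topology (narrow-exchange) attempts per locus per sweep.
#' @param tune Auto-tune step sizes during burn-in?
#' @param preset `"simulation"` (default) or `"empirical"`.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(burnin = NULL, nsamples = NULL, thin = NULL,
                        seed = 1, nexch = 2, tune = TRUE,
                        preset = c("simulation", "empirical")) {
  preset <- match.arg(preset)
  def <- if (preset == "simulation") {
    list(burnin = 20000L, nsamples = 200000L, thin = 2L)
  } else {
    list(burnin = 200000L, nsamples = 10000L, thin = 200L)
  }
  structure(list(
    burnin = as.integer(burnin %||% def$burnin),
    nsamples = as.integer(nsamples %||% def$nsamples),
    thin = as.integer(thin %||% def$thin),
    seed = as.integer(seed),
    nexch = as.integer(nexch),
    tune = isTRUE(tune)
  ), class = "mcmc_config")
}

# map one locus (alignment + imap) plus an initial simulated gene tree into
# the 0-based arrays the compiled sampler consumes
locus_payload <- function(locus, imap, net, pg, init_seed, gt = NULL) {
  aln <- locus$alignment
  tags <- rownames(aln)
  sp <- imap$species[match(tags, imap$tag)]
  if (anyNA(sp)) {
    stop_mscoal("alignment tag(s) missing from the Imap: ",
                paste(tags[is.na(sp)], collapse = ", "))
  }
  if (length(tags) < 2) stop_mscoal("each locus needs at least 2 sequences")
  cfg <- tibble::tibble(tag = tags, species = sp)
  class(cfg) <- c("sample_config", class(cfg))
  if (is.null(gt)) gt <- simulate_gene_tree(net, cfg, seed = init_seed)
  if (!identical(gt$nodes$label[seq_along(tags)], tags)) {
    stop_mscoal("gene-tree tip order does not match the alignment rows")
  }

  code <- matrix(match(aln, c("A", "C", "G", "T")) - 1L, nrow(aln), ncol(aln))
  key <- apply(code, 2, paste, collapse = ",")
  uniq <- which(!duplicated(key))
  wt <- as.vector(table(factor(key, levels = key[uniq])))
  pat <- code[, uniq, drop = FALSE]

  nnode <- nrow(gt$nodes)
  H <- nrow(pg$phi)
  choice <- matrix(-1L, nnode, max(H, 1L))
  if (H > 0 && nrow(gt$choices)) {
    hix <- match(gt$choices$phi_param, pg$phi$param)
    choice[cbind(gt$choices$node, hix)] <-
      ifelse(gt$choices$choice == "donor", 1L, 0L)
  }
  pop_ix <- match(gt$nodes$pop, pg$pops$pop) - 1L
  list(
    pat = pat, wt = as.numeric(wt),
    parent = ifelse(is.na(gt$nodes$parent), -1L,
                    as.integer(gt$nodes$parent) - 1L),
    age = gt$nodes$age,
    pop = pop_ix,
    choice = choice
  )
}

build_engine <- function(pg, priors) {
  pops <- pg$pops
  tau_ix <- stats::setNames(seq_len(nrow(pg$tau)) - 1L, pg$tau$param)
  phi_ix <- stats::setNames(seq_len(nrow(pg$phi)) - 1L, pg$phi$param)
  list(
    lo_tau = as.integer(ifelse(is.na(pops$lo_tau), -1L, tau_ix[pops$lo_tau])),
    hi_tau = as.integer(ifelse(is.na(pops$hi_tau), -1L, tau_ix[pops$hi_tau])),
    theta_ix = as.integer(pops$id - 1L),
    trans = as.integer(match(pops$trans, c("root", "single", "choice")) - 1L),
    to1 = as.integer(ifelse(is.na(pops$to1), -1L, pops$to1 - 1L)),
    to2 = as.integer(ifelse(is.na(pops$to2), -1L, pops$to2 - 1L)),
    phi_ix = as.integer(ifelse(is.na(pops$phi), -1L, phi_ix[pops$phi])),
    tau = as.double(pg$tau$value),
    theta = as.double(pops$theta),
    phi = as.double(pg$phi$value),
    root_tau = as.integer(unname(tau_ix[pg$root_tau])),
    n_other = as.integer(nrow(pg$tau) - 1L),
    prior_a_theta = as.double(priors$alpha),
    prior_b_theta = as.double(rep(priors$beta_theta, nrow(pops))),
    prior_a_tau = as.double(priors$alpha),
    prior_b_tau = as.double(priors$beta_tau)
  )
}

# evaluate the compiled core's likelihood and coalescent density on explicit
# gene trees (used to cross-check against the R reference implementations)
eval_state_core <- function(loci, gts, imap, net, priors) {
  pg <- net_pop_graph(net)
  engine <- build_engine(pg, priors)
  payloads <- lapply(seq_along(loci), function(i) {
    locus_payload(loci[[i]], imap, net, pg, init_seed = 0L, gt = gts[[i]])
  })
  res <- eval_state_cpp(engine, payloads)
  tibble::tibble(lnl = res$lnl, logdens = res$logdens)
}

#' Run the MCMC sampler under the MSC or MSci model
#'
#' Samples divergence times (`tau_*`), population sizes (`theta_*`, one per
#' branch of the network, hybrid segments included) and introgression
#' probabilities (`phi_*`, MSci only), integrating over per-locus gene trees
#' (topologies, coalescent times and introgression paths). The network
#' topology is fixed; under `model = "msci"` the introgression events must
#' be specified a priori on `net`. Initial parameter values are `net`'s
#' annotated ages and thetas; initial gene trees are simulated from the
#' model at those values.
#'
#' @param loci List of [locus_data] (or a single one).
#' @param imap A [sample_config] mapping sequence tags to species.
#' @param net A [species_network]: the inference model (plain tree for MSC,
#'   with hybrid edges for MSci; migration bands are not supported in
#'   inference).
#' @param model `"msc"` or `"msci"`; checked against `net`.
#' @param priors A [prior_spec].
#' @param config An [mcmc_config].
#' @param beta Likelihood power (1 = posterior; used by stepping-stone
#'   power posteriors).
#' @param likelihood If `FALSE` the sequence likelihood is switched off and
#'   the chain samples from the prior (used for prior-recovery checks).
#' @return A tibble of class `mscoal_trace`: one row per posterior sample,
#'   one column per scalar parameter plus `lnL` (sequence log-likelihood)
#'   and `logdens` (gene-tree log-density), with run metadata in attributes.
#' @export
run_mcmc <- function(loci, imap, net, model = c("msc", "msci"),
                     priors, config = mcmc_config(), beta = 1,
                     likelihood = TRUE) {
  model <- match.arg(model)
  if (nrow(net$bands)) {
    stop_mscoal("inference with migration bands is not supported; ",
                "use an MSci network to approximate continuous gene flow")
  }
  if (model == "msci" && nrow(net$hybrids) == 0) {
    stop_mscoal("model 'msci' requires hybrid edges on the network")
  }
  if (model == "msc" && nrow(net$hybrids) > 0) {
    stop_mscoal("model 'msc' requires a network without hybrid edges")
  }
  stopifnot(inherits(priors, "prior_spec"), inherits(config, "mcmc_config"))
  if (inherits(loci, "locus_data")) loci <- list(loci)

  pg <- net_pop_graph(net)
  engine <- build_engine(pg, priors)

  if (length(loci)) {
    payloads <- lapply(seq_along(loci), function(i) {
      locus_payload(loci[[i]], imap, net, pg,
                    init_seed = locus_seed(config$seed + 104729L, i))
    })
  } else {
    payloads <- list()
  }

  res <- run_mcmc_cpp(engine, payloads, list(
    seed = as.double(config$seed),
    beta = as.double(beta),
    likelihood = isTRUE(likelihood) && length(loci) > 0,
    burnin = config$burnin,
    nsamples = config$nsamples,
    thin = config$thin,
    tune = config$tune,
    nexch = config$nexch
  ))
  if (is.finite(res$audit) && res$audit > 1e-6) {
    warning("sampler cache audit discrepancy: ", format(res$audit))
  }

  cols <- c(pg$tau$param, paste0("theta_", pg$pops$pop),
            if (nrow(pg$phi)) pg$phi$param, "lnL", "logdens")
  samples <- res$samples
  colnames(samples) <- cols
  trace <- tibble::as_tibble(as.data.frame(samples))
  attr(trace, "model") <- model
  attr(trace, "priors") <- priors
  attr(trace, "config") <- config
  attr(trace, "acc") <- res$acc
  attr(trace, "audit") <- res$audit
  attr(trace, "network") <- write_network(net)
  class(trace) <- c("mscoal_trace", class(trace))
  trace
}

#' Parameter columns of a trace (excluding bookkeeping columns)
#' @param trace An `mscoal_trace` (or any data frame of samples).
#' @return Character vector of parameter column names.
#' @export
trace_parameters <- function(trace) {
  setdiff(names(trace), c("lnL", "logdens", "sample"))
}

#' Write / read a posterior trace as TSV
#'
#' One row per posterior sample, one column per parameter; run metadata
#' (model, seed, network) is stored in `#`-prefixed header lines.
#'
#' @param trace An `mscoal_trace`.
#' @param path File path.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- attr(trace, "config")
  meta <- list(model = attr(trace, "model"),
               seed = if (!is.null(cfg)) cfg$seed,
               network = attr(trace, "network"))
  meta <- meta[!vapply(meta, is.null, TRUE)]
  for (nm in names(meta)) {
    writeLines(paste0("# ", nm, "=", meta[[nm]]), con)
  }
  utils::write.table(as.data.frame(trace), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", check.names = FALSE)
  trace <- tibble::as_tibble(tab)
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    k <- sub("=.*$", "", kv)
    v <- sub("^[^=]*=", "", kv)
    attr(trace, k) <- v
  }
  class(trace) <- c("mscoal_trace", class(trace))
  trace
}

#' Effective sample size of a (possibly autocorrelated) sample
#'
#' Initial positive sequence estimator on the autocorrelation function.
#'
#' @param x Numeric vector of MCMC draws.
#' @return Estimated effective sample size (capped at `length(x)`).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(1)
  maxlag <- min(n - 2, 2000L)
  ac <- stats::acf(x, lag.max = maxlag, plot = FALSE)$acf[-1]
  s <- 0
  k <- 1
  while (k + 1 <= length(ac)) {
    pair <- ac[k] + ac[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, min(n, n / (1 + 2 * s)))
}

#' Compare independent MCMC runs
#'
#' Per-parameter across-run consistency: the largest difference between run
#' means in pooled posterior-standard-deviation units, effective sample
#' sizes, and a bimodality flag (bimodality coefficient > 5/9 on the pooled
#' draws, the value attained by the uniform distribution).
#'
#' @param traces A list of >= 2 `mscoal_trace` objects from the same model.
#' @return A tibble with one row per parameter.
#' @export
convergence_check <- function(traces) {
  if (inherits(traces, "mscoal_trace")) {
    stop_mscoal("convergence_check needs a list of >= 2 traces")
  }
  if (length(traces) < 2) stop_mscoal("need at least 2 traces")
  models <- unique(vapply(traces, function(t) {
    as.character(attr(t, "model") %||% NA_character_)
  }, ""))
  if (length(stats::na.omit(models)) > 1) {
    stop_mscoal("traces come from different models: ",
                paste(models, collapse = ", "))
  }
  pars <- trace_parameters(traces[[1]])
  purrr::map_dfr(pars, function(p) {
    draws <- lapply(traces, function(t) t[[p]])
    means <- vapply(draws, mean, 0)
    pooled <- unlist(draws)
    psd <- stats::sd(pooled)
    disc <- if (psd > 0) (max(means) - min(means)) / psd else 0
    g1 <- mean((pooled - mean(pooled))^3) / psd^3
    g2 <- mean((pooled - mean(pooled))^4) / psd^4
    bc <- if (psd > 0) (g1^2 + 1) / g2 else 0
    tibble::tibble(
      parameter = p,
      mean = mean(pooled),
      sd = psd,
      discrepancy = disc,
      ess = sum(vapply(draws, ess, 0)),
      bimodal = is.finite(bc) && bc > 5 / 9
    )
  })
}
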