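#' Benchmark species networks for the three gene-flow scenarios
#'
#' Builds the three four-species benchmark networks used throughout the
#' simulation study: gene flow (a) between sister species (B into A), (b)
#' between non-sister species (D into C), and (c) from an unsampled ghost
#' outgroup (O into A). The species tree is (((A,B)t, C)s, D)r with node ages
#' `tau_t = 1*theta`, `tau_s = 2*theta`, `tau_r = 3*theta` (the ghost
#' scenario adds O diverging at `4*theta`), and a constant population size
#' `theta` on all branches. Divergence times are proportional to `theta`.
#'
#' Under `mode = "msci"` the gene flow is one episodic introgression event
#' with probability `rate` (= phi) at time `tau_h = 0.5*theta`, inside both
#' branches involved; at this depth, ignoring the non-sister event biases
#' the estimated age of the donor-recipient ancestor by roughly -15%% and
#' -50%% at phi = 0.05 and 0.2, the benchmark bias levels these scenarios
#' are designed to exhibit.
#'
#' Under `mode = "im"` the same donor/recipient pair is connected
#' by a continuous migration band with `rate` (= M = Nm) migrants per
#' generation over the species' full coexistence: duration `1*theta` for the
#' sister and ghost scenarios and `2*theta` for non-sister, which at
#' `theta = 0.01` gives expected cumulative introgression proportions
#' `phi0 = 1 - exp(-4 M dtau / theta)` of 0.33/0.98 (M = 0.1/1) and
#' 0.55/1.00 respectively. `mode = "msc"` returns the plain species tree a
#' gene-flow-blind analysis assumes (without the ghost tip).
#'
#' @param scenario One of `"sister"`, `"nonsister"`, `"ghost"`.
#' @param theta Constant population size parameter (study grid: 0.001, 0.01).
#' @param rate Introgression probability phi (msci; grid: 0.05, 0.2) or
#'   migration rate M = Nm (im; grid: 0.1, 1). Ignored for `mode = "msc"`.
#' @param mode One of `"msci"`, `"im"`, `"msc"`.
#' @return A [species_network].
#' @examples
#' scenario_network("sister", theta = 0.01, rate = 0.2, mode = "msci")
#' @export
scenario_network <- function(scenario = c("sister", "nonsister", "ghost"),
                             theta, rate = NULL,
                             mode = c("msci", "im", "msc")) {
  scenario <- match.arg(scenario)
  mode <- match.arg(mode)
  if (!is_scalar_number(theta) || theta <= 0) {
    stop_mscoal("theta must be a positive number")
  }
  if (mode != "msc") {
    if (!is_scalar_number(rate) || rate < 0) {
      stop_mscoal("rate (phi or M) must be a non-negative number")
    }
    if (mode == "msci" && rate > 1) stop_mscoal("phi must lie in [0, 1]")
  }

  tau_t <- 1 * theta
  tau_s <- 2 * theta
  tau_r <- 3 * theta
  tau_z <- 4 * theta # ghost outgroup divergence
  tau_h <- 0.5 * theta # introgression time, inside both branches involved

  base <- tibble::tibble(
    name   = c("A", "B", "C", "D", "t", "s", "r"),
    parent = c("t", "t", "s", "r", "s", "r", NA),
    age    = c(0, 0, 0, 0, tau_t, tau_s, tau_r),
    theta  = theta,
    ghost  = FALSE
  )
  flow <- switch(scenario,
    sister    = list(donor_tip = "B", recipient_tip = "A"),
    nonsister = list(donor_tip = "D", recipient_tip = "C"),
    ghost     = list(donor_tip = "O", recipient_tip = "A")
  )
  if (scenario == "ghost") {
    base$parent[base$name == "r"] <- "z"
    base <- dplyr::bind_rows(base, tibble::tibble(
      name = c("O", "z"), parent = c("z", NA), age = c(0, tau_z),
      theta = theta, ghost = c(TRUE, FALSE)
    ))
  }

  if (mode == "msc") {
    plain <- base[!base$ghost & base$name != "z", ]
    plain$parent[plain$name == "r"] <- NA
    return(species_network(plain))
  }

  if (mode == "im") {
    bands <- tibble::tibble(donor = flow$donor_tip,
                            recipient = flow$recipient_tip,
                            rate = rate, start = NA_real_, end = NA_real_)
    return(species_network(base, bands = bands))
  }

  # msci: insert the recipient-side node h (on the recipient branch) and the
  # donor-side node g (on the donor branch), both at tau_h
  nodes <- base
  splice <- function(nodes, tip, new_name) {
    old_parent <- nodes$parent[nodes$name == tip]
    nodes$parent[nodes$name == tip] <- new_name
    dplyr::bind_rows(nodes, tibble::tibble(
      name = new_name, parent = old_parent, age = tau_h,
      theta = theta, ghost = FALSE
    ))
  }
  nodes <- splice(nodes, flow$recipient_tip, "h")
  nodes <- splice(nodes, flow$donor_tip, "g")
  hyb <- tibble::tibble(label = "H1", donor = "g", recipient = "h",
                        phi = rate)
  species_network(nodes, hybrids = hyb)
}

#' Specify one simulation condition
#'
#' One cell of the simulation grid: a gene-flow scenario, the generating
#' model, and the data dimensions.
#'
#' @param scenario `"sister"`, `"nonsister"` or `"ghost"`.
#' @param mode Generating model: `"msci"` (episodic introgression) or `"im"`
#'   (continuous migration); `"msc"` simulates without gene flow.
#' @param theta Population size parameter (grid: 0.001 or 0.01).
#' @param rate phi (msci) or M (im); ignored for msc.
#' @param nloci Number of unlinked loci (default 1000).
#' @param L Sites per locus (grid: 100 or 500).
#' @param nseq Haploid sequences per sampled species (grid: 2 or 10).
#' @param replicate Replicate index (1..10 in the study design).
#' @param seed Integer seed for the dataset.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario, mode, theta, rate = NULL, nloci = 1000,
                          L = 500, nseq = 2, replicate = 1, seed = 1) {
  scenario <- match.arg(scenario, c("sister", "nonsister", "ghost"))
  mode <- match.arg(mode, c("msci", "im", "msc"))
  if (mode != "msc" && is.null(rate)) {
    stop_mscoal("rate (phi for msci, M for im) is required for mode '",
                mode, "'")
  }
  structure(list(
    scenario = scenario, mode = mode, theta = theta, rate = rate,
    nloci = as.integer(nloci), L = as.integer(L), nseq = as.integer(nseq),
    replicate = as.integer(replicate), seed = as.integer(seed)
  ), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec> %s/%s theta=%g rate=%s: %d loci x %d bp, %d seq/species, replicate %d, seed %d\n",
    x$scenario, x$mode, x$theta,
    if (is.null(x$rate)) "-" else format(x$rate),
    x$nloci, x$L, x$nseq, x$replicate, x$seed
  ))
  invisible(x)
}

#' Generate one simulated dataset
#'
#' Simulates `nloci` gene trees on the scenario network, evolves JC69
#' sequences on each, and writes the dataset to `dir`: `data.phy` (stacked
#' sequential PHYLIP), `imap.txt`, `genetrees.nwk` and `truth.json` (the
#' generating parameter values, sufficient to score estimates against the
#' truth). Fully reproducible from `spec$seed`; locus `i` uses substream
#' `(seed, i)`.
#'
#' @param spec A [scenario_spec].
#' @param dir Output directory (created if needed). `NULL` returns the data
#'   in memory without writing.
#' @return Invisibly, a list with `net`, `cfg`, `gene_trees`, `loci`,
#'   `truth`, and (if written) the file `paths`.
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  net <- scenario_network(spec$scenario, spec$theta, spec$rate, spec$mode)
  tips <- network_tips(net, include_ghost = FALSE)
  cfg <- sample_config(stats::setNames(rep(spec$nseq, length(tips)), tips))
  gts <- vector("list", spec$nloci)
  loci <- vector("list", spec$nloci)
  for (i in seq_len(spec$nloci)) {
    set.seed(locus_seed(spec$seed, i))
    gts[[i]] <- simulate_gene_tree(net, cfg)
    loci[[i]] <- evolve_jc69(gts[[i]], spec$L)
  }
  truth <- truth_record(spec, net)
  out <- list(net = net, cfg = cfg, gene_trees = gts, loci = loci,
              truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      data = file.path(dir, "data.phy"),
      imap = file.path(dir, "imap.txt"),
      genetrees = file.path(dir, "genetrees.nwk"),
      truth = file.path(dir, "truth.json")
    )
    write_phylip_multilocus(loci, paths$data)
    write_imap(cfg, paths$imap)
    write_genetrees(gts, paths$genetrees)
    write_truth(truth, paths$truth)
    out$paths <- paths
  }
  invisible(out)
}

#' Truth records
#'
#' The generating parameter values of one simulated dataset, keyed by the
#' same parameter names the sampler reports (`tau_*`, `theta_*`, `phi_*`),
#' plus the scenario specification.
#'
#' @param spec A [scenario_spec].
#' @param net The generating [species_network].
#' @return A list of class `truth_record` with elements `spec`, `params`
#'   (named numeric vector), `network` (extended-Newick string) and `bands`.
#' @export
truth_record <- function(spec, net) {
  pg <- build_pop_graph(net)
  params <- c(
    stats::setNames(pg$tau$value, pg$tau$param),
    stats::setNames(pg$pops$theta, paste0("theta_", pg$pops$pop)),
    if (nrow(pg$phi)) stats::setNames(pg$phi$value, pg$phi$param)
  )
  structure(list(
    spec = unclass(spec),
    params = params,
    network = write_network(net),
    bands = as.data.frame(net$bands)
  ), class = "truth_record")
}

#' @rdname truth_record
#' @param truth A `truth_record`.
#' @param path JSON file path.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$params <- as.list(x$params) # keep parameter names in the JSON object
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname truth_record
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$spec <- do.call(scenario_spec, x$spec[!vapply(x$spec, is.null, TRUE)])
  x$params <- unlist(x$params)
  x$bands <- as.data.frame(x$bands)
  structure(x, class = "truth_record")
}

#' The full simulation grid
#'
#' The factorial study design: 3 scenarios x 2 generating models (msci, im)
#' x 2 theta x 2 rates x 2 sequence lengths x 2 sample sizes x 10
#' replicates = 960 dataset specifications, each with a distinct seed.
#'
#' @param base_seed Integer; dataset seeds are `base_seed + 1 ... + 960`.
#' @return A tibble with one row per dataset specification.
#' @export
replicate_grid <- function(base_seed = 0) {
  grid <- tidyr::expand_grid(
    scenario = c("sister", "nonsister", "ghost"),
    mode = c("msci", "im"),
    theta = c(0.001, 0.01),
    rate_level = c("low", "high"),
    L = c(100L, 500L),
    nseq = c(2L, 10L),
    replicate = 1:10
  )
  grid$rate <- ifelse(grid$mode == "msci",
                      ifelse(grid$rate_level == "low", 0.05, 0.2),
                      ifelse(grid$rate_level == "low", 0.1, 1.0))
  grid$nloci <- 1000L
  grid$seed <- as.integer(base_seed) + seq_len(nrow(grid))
  dplyr::select(grid, "scenario", "mode", "theta", "rate", "nloci", "L",
                "nseq", "replicate", "seed")
}
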