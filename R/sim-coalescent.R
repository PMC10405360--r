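#' Simulate a gene tree under the MSC, MSci or IM model
#'
#' Simulates one per-locus genealogy backward in time on a species network.
#' Within a population of size `theta`, each pair of lineages coalesces at
#' rate `2/theta` per tau unit. At an introgression event at time `tau_h`,
#' each lineage in the recipient population independently takes the donor
#' path with probability `phi` (the choice is recorded per lineage). While a
#' migration band donor -> recipient with rate `M = Nm` is active, each
#' lineage currently in the recipient population jumps (backward in time)
#' into the donor population at rate `4*M/theta_recipient` per tau unit, so
#' the probability of escaping migration over a duration `dtau` is
#' `exp(-4*M*dtau/theta)`.
#'
#' Waiting times are propagated across population boundaries by exponential
#' budget carrying (no draw is discarded at a boundary), and choices with
#' `phi` equal to 0 or 1 consume no randomness. Consequently a network whose
#' introgression probabilities are all 0, or whose migration rates are all 0,
#' yields seed-for-seed identical gene trees to the plain MSC on the
#' underlying species tree.
#'
#' @param net A [species_network].
#' @param cfg A [sample_config]; tags must map to sampled tips of `net`.
#' @param mode One of `"auto"`, `"msc"`, `"msci"`, `"im"`. Modes other than
#'   `"auto"` additionally assert that the network matches the model (e.g.
#'   `"im"` requires migration bands and no hybrid edges).
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @return A `gene_tree`: list with tibbles `nodes` (id, parent, age, pop,
#'   label, species), `choices` (one row per lineage decision at a hybrid
#'   edge) and `events` (logged migration events).
#' @export
simulate_gene_tree <- function(net, cfg, mode = c("auto", "msc", "msci", "im"),
                               seed = NULL) {
  mode <- match.arg(mode)
  has_hyb <- nrow(net$hybrids) > 0
  has_band <- nrow(net$bands) > 0
  if (mode == "msci" && has_band) {
    stop_mscoal("MSci simulation requires a network without migration bands")
  }
  if (mode == "im" && (has_hyb || !has_band)) {
    stop_mscoal("IM simulation requires migration bands and no hybrid edges")
  }
  if (mode == "msc" && (has_hyb || has_band)) {
    stop_mscoal("MSC simulation requires a plain species tree")
  }
  validate_config(cfg, net)
  if (nrow(cfg) == 0) stop_mscoal("no lineages sampled")
  if (!is.null(seed)) set.seed(seed)

  pg <- net_pop_graph(net)
  pops <- pg$pops
  P <- nrow(pops)
  phi_val <- stats::setNames(pg$phi$value, pg$phi$param)
  hyb_label <- stats::setNames(pg$phi$label, pg$phi$param)
  bands <- pg$bands

  ntip <- nrow(cfg)
  nnode <- 2L * ntip - 1L
  tip_pop <- unname(pg$tip_pop[cfg$species])
  born_pop <- c(tip_pop, rep(NA_integer_, nnode - ntip)) # pop at node's age
  pop <- born_pop                                        # lineage's current pop
  parent <- rep(NA_integer_, nnode)
  age <- c(rep(0, ntip), rep(NA_real_, nnode - ntip))
  active <- seq_len(ntip)
  nxt <- ntip + 1L

  ch_node <- integer(); ch_param <- character(); ch_choice <- character()
  ev_time <- numeric(); ev_node <- integer(); ev_from <- integer()
  ev_to <- integer()

  boundaries <- sort(unique(c(
    pops$hi_age[is.finite(pops$hi_age)], bands$start, bands$end
  )))
  boundaries <- boundaries[boundaries > 0]

  t <- 0
  budget <- stats::rexp(1)
  tol <- 1e-12

  while (length(active) > 1L) {
    tnext <- boundaries[boundaries > t + tol]
    tnext <- if (length(tnext)) tnext[1] else Inf

    # enumerate candidate events in a fixed order: coalescible pairs by
    # (i, j) ascending, then (band, lineage) migrations
    k <- length(active)
    pr_i <- integer(0); pr_j <- integer(0); pr_rate <- numeric(0)
    if (k > 1) {
      for (a in 1:(k - 1)) {
        for (b in (a + 1):k) {
          if (pop[active[a]] == pop[active[b]]) {
            pr_i <- c(pr_i, a); pr_j <- c(pr_j, b)
            pr_rate <- c(pr_rate, 2 / pops$theta[pop[active[a]]])
          }
        }
      }
    }
    mg_band <- integer(0); mg_l <- integer(0); mg_rate <- numeric(0)
    if (nrow(bands)) {
      for (bi in seq_len(nrow(bands))) {
        if (bands$start[bi] <= t + tol && tnext <= bands$end[bi] + tol) {
          inrec <- which(pop[active] == bands$recipient[bi])
          for (a in inrec) {
            mg_band <- c(mg_band, bi); mg_l <- c(mg_l, a)
            mg_rate <- c(mg_rate, 4 * bands$rate[bi] /
                           pops$theta[bands$recipient[bi]])
          }
        }
      }
    }
    rates <- c(pr_rate, mg_rate)
    rtot <- sum(rates)

    span <- tnext - t
    if (rtot <= 0 || budget > rtot * span) {
      if (!is.finite(tnext)) {
        stop_mscoal("simulation stalled: lineages cannot coalesce ",
                    "(theta <= 0 on a reachable population?)")
      }
      budget <- budget - rtot * span
      t <- tnext
      # population transitions for lineages whose population ends at t
      for (a in seq_along(active)) {
        v <- active[a]
        while (is.finite(pops$hi_age[pop[v]]) &&
               pops$hi_age[pop[v]] <= t + tol) {
          p <- pop[v]
          if (pops$trans[p] == "single") {
            pop[v] <- pops$to1[p]
          } else if (pops$trans[p] == "choice") {
            ph <- phi_val[[pops$phi[p]]]
            take <- if (ph >= 1) TRUE else if (ph <= 0) FALSE else
              stats::runif(1) < ph
            pop[v] <- if (take) pops$to1[p] else pops$to2[p]
            ch_node <- c(ch_node, v)
            ch_param <- c(ch_param, pops$phi[p])
            ch_choice <- c(ch_choice, if (take) "donor" else "recipient")
          } else {
            break
          }
        }
      }
      next
    }

    # an event fires within this interval
    t <- t + budget / rtot
    budget <- stats::rexp(1)
    u <- stats::runif(1) * rtot
    cum <- cumsum(rates)
    ev <- which(u <= cum)[1]
    if (ev <= length(pr_rate)) {
      a <- pr_i[ev]; b <- pr_j[ev]
      v <- active[a]; w <- active[b]
      parent[v] <- nxt; parent[w] <- nxt
      age[nxt] <- t
      born_pop[nxt] <- pop[v]
      pop[nxt] <- pop[v]
      active <- c(active[-c(a, b)], nxt)
      nxt <- nxt + 1L
    } else {
      m <- ev - length(pr_rate)
      v <- active[mg_l[m]]
      to <- bands$donor[mg_band[m]]
      ev_time <- c(ev_time, t); ev_node <- c(ev_node, v)
      ev_from <- c(ev_from, pop[v]); ev_to <- c(ev_to, to)
      pop[v] <- to
    }
  }

  pad <- rep(NA_character_, nnode - ntip)
  nodes <- tibble::new_tibble(list(
    id = seq_len(nnode),
    parent = parent,
    age = age,
    pop = pops$pop[born_pop],
    label = c(cfg$tag, pad),
    species = c(cfg$species, pad)
  ), nrow = nnode)
  choices <- tibble::new_tibble(list(
    node = ch_node,
    phi_param = ch_param,
    hybrid = unname(hyb_label[ch_param]) %||% character(),
    choice = ch_choice
  ), nrow = length(ch_node))
  events <- tibble::new_tibble(list(
    time = ev_time,
    event = rep("migration", length(ev_node)),
    node = ev_node,
    from = pops$pop[ev_from],
    to = pops$pop[ev_to]
  ), nrow = length(ev_node))
  structure(list(nodes = nodes, choices = choices, events = events),
            class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  ntip <- sum(!is.na(x$nodes$label))
  cat("<gene_tree> ", ntip, " tips, MRCA age ",
      format(max(x$nodes$age)), sep = "")
  if (nrow(x$choices)) cat(", ", nrow(x$choices), " introgression choice(s)")
  if (nrow(x$events)) cat(", ", nrow(x$events), " migration event(s)")
  cat("\n")
  invisible(x)
}

#' Simulate a set of unlinked loci
#'
#' Loci are independent draws (free recombination between loci, none within).
#' Locus `i` is generated from a substream seed derived from `(seed, i)`, so
#' it does not depend on `nloci`.
#'
#' @inheritParams simulate_gene_tree
#' @param nloci Number of loci (>= 1).
#' @param seed Integer base seed (required, for reproducibility).
#' @return A list of `gene_tree` objects, of length `nloci`.
#' @export
simulate_locus_set <- function(net, cfg, nloci, seed,
                               mode = c("auto", "msc", "msci", "im")) {
  mode <- match.arg(mode)
  if (nloci < 1) stop_mscoal("nloci must be >= 1")
  lapply(seq_len(nloci), function(i) {
    simulate_gene_tree(net, cfg, mode = mode, seed = locus_seed(seed, i))
  })
}

#' Convert a gene tree to an ape `phylo` object
#'
#' Branch lengths are age differences (tau units, i.e. expected
#' substitutions per site under the strict clock).
#'
#' @param x A `gene_tree`.
#' @param ... Unused.
#' @return An object of class `phylo`.
#' @exportS3Method ape::as.phylo
as.phylo.gene_tree <- function(x, ...) {
  nd <- x$nodes
  ntip <- sum(!is.na(nd$label))
  if (ntip == 1L) stop_mscoal("cannot convert a single-tip gene tree")
  nnode <- nrow(nd)
  # ape wants tips 1..ntip, root ntip+1, internals following
  internal <- which(is.na(nd$label))
  root <- which(is.na(nd$parent))
  remap <- integer(nnode)
  remap[seq_len(ntip)] <- seq_len(ntip)
  remap[root] <- ntip + 1L
  rest <- setdiff(internal, root)
  remap[rest] <- ntip + 1L + seq_along(rest)
  has_par <- which(!is.na(nd$parent))
  edge <- cbind(remap[nd$parent[has_par]], remap[has_par])
  elen <- nd$age[nd$parent[has_par]] - nd$age[has_par]
  phy <- structure(list(
    edge = edge,
    edge.length = elen,
    tip.label = nd$label[seq_len(ntip)],
    Nnode = nnode - ntip
  ), class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Write gene trees to a Newick file
#'
#' @param gts A list of `gene_tree` objects (or a single one).
#' @param path Output file; one Newick string per line.
#' @export
write_genetrees <- function(gts, path) {
  if (inherits(gts, "gene_tree")) gts <- list(gts)
  phys <- lapply(gts, as.phylo.gene_tree)
  class(phys) <- "multiPhylo"
  ape::write.tree(phys, file = path)
  invisible(path)
}

#' Per-locus event log as a tibble
#'
#' @param gts List of `gene_tree`s.
#' @return Tibble with columns `locus`, `time`, `event`, `node`, `from`, `to`.
#' @export
event_log <- function(gts) {
  if (inherits(gts, "gene_tree")) gts <- list(gts)
  purrr::imap_dfr(gts, function(g, i) {
    if (nrow(g$events) == 0) return(NULL)
    dplyr::mutate(g$events, locus = i, .before = 1)
  })
}
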