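#' Species networks with introgression edges and migration bands
#'
#' A species network is a rooted, ultrametric species tree whose nodes carry
#' ages (`tau`, in expected substitutions per site) and mutation-scaled
#' population sizes (`theta` = 4*N*mu, the expected number of substitutions
#' per site between two sequences from the population), plus optional
#' episodic introgression (hybrid) edges and continuous migration bands.
#'
#' Each branch of the tree is a population, named after the node at its
#' bottom end; the root node names the (unbounded) root population. An
#' introgression event at time `tau_h` is represented by a pair of degree-two
#' nodes inserted on the two branches involved: the recipient-side node (`h`)
#' on the branch receiving genes and the donor-side node (`g`) on the branch
#' donating them, both at the same age. Backward in time, a lineage reaching
#' `h` traces into the donor population with probability `phi` and stays with
#' probability `1 - phi`.
#'
#' @param nodes A data frame with columns `name`, `parent` (parent node name,
#'   `NA` for the root), `age` (>= 0; 0 at tips), `theta` (> 0), and
#'   optionally `ghost` (logical; an extant population that contributes no
#'   samples).
#' @param hybrids Optional data frame of introgression edges with columns
#'   `label` (e.g. `"H1"`), `donor` (name of the donor-side node `g`),
#'   `recipient` (name of the recipient-side node `h`), and `phi`.
#' @param bands Optional data frame of migration bands with columns `donor`,
#'   `recipient` (population/node names), `rate` (M = Nm migrants per
#'   generation), and optionally `start`, `end` (tau units; default is the
#'   full overlap of the two populations' lifespans).
#' @return An object of class `species_network`.
#' @examples
#' net <- species_network(tibble::tibble(
#'   name   = c("A", "B", "r"),
#'   parent = c("r", "r", NA),
#'   age    = c(0, 0, 0.01),
#'   theta  = 0.01
#' ))
#' @export
species_network <- function(nodes, hybrids = NULL, bands = NULL) {
  nodes <- tibble::as_tibble(nodes)
  req <- c("name", "parent", "age", "theta")
  if (!all(req %in% names(nodes))) {
    stop_mscoal("`nodes` needs columns: ", paste(req, collapse = ", "))
  }
  if (!"ghost" %in% names(nodes)) nodes$ghost <- FALSE
  nodes$ghost[is.na(nodes$ghost)] <- FALSE
  nodes <- nodes[, c("name", "parent", "age", "theta", "ghost")]

  empty_hyb <- tibble::tibble(
    label = character(), donor = character(),
    recipient = character(), phi = numeric()
  )
  empty_band <- tibble::tibble(
    donor = character(), recipient = character(),
    rate = numeric(), start = numeric(), end = numeric()
  )
  hybrids <- if (is.null(hybrids) || nrow(hybrids) == 0) empty_hyb else
    tibble::as_tibble(hybrids)[, names(empty_hyb)]
  bands <- if (is.null(bands) || nrow(bands) == 0) empty_band else {
    bands <- tibble::as_tibble(bands)
    if (!"start" %in% names(bands)) bands$start <- NA_real_
    if (!"end" %in% names(bands)) bands$end <- NA_real_
    bands[, names(empty_band)]
  }

  net <- structure(
    list(nodes = nodes, hybrids = hybrids, bands = bands),
    class = "species_network"
  )
  net <- validate_network(net)
  attr(net, "pg_cache") <- new.env(parent = emptyenv())
  net
}

validate_network <- function(net) {
  nodes <- net$nodes
  if (anyDuplicated(nodes$name)) {
    stop_mscoal("duplicate node names: ",
                paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "))
  }
  root <- nodes$name[is.na(nodes$parent)]
  if (length(root) != 1L) {
    stop_mscoal("network must have exactly one root, found ", length(root))
  }
  known <- !is.na(nodes$parent) & !(nodes$parent %in% nodes$name)
  if (any(known)) {
    stop_mscoal("unknown parent for node ", nodes$name[which(known)[1]])
  }
  age <- stats::setNames(nodes$age, nodes$name)
  if (any(nodes$age < 0)) stop_mscoal("negative node age")
  bad <- !is.na(nodes$parent) & nodes$age >= age[nodes$parent] - 0
  if (any(bad)) {
    stop_mscoal("node ", nodes$name[which(bad)[1]],
                " is not younger than its parent")
  }
  nkids <- table(factor(nodes$parent, levels = nodes$name))
  tips <- nodes$name[nkids[nodes$name] == 0]
  if (any(abs(age[tips]) > 1e-9)) {
    stop_mscoal("network is not ultrametric: tip ",
                tips[which(abs(age[tips]) > 1e-9)[1]], " has age > 0")
  }
  if (any(!is.finite(nodes$theta)) || any(nodes$theta <= 0)) {
    stop_mscoal("theta must be positive for every population")
  }

  hyb <- net$hybrids
  if (nrow(hyb)) {
    if (any(hyb$phi < 0 | hyb$phi > 1)) {
      stop_mscoal("phi must lie in [0, 1]")
    }
    for (i in seq_len(nrow(hyb))) {
      d <- hyb$donor[i]; r <- hyb$recipient[i]
      if (!all(c(d, r) %in% nodes$name)) {
        stop_mscoal("hybrid edge ", hyb$label[i], " references unknown nodes")
      }
      if (abs(age[d] - age[r]) > 1e-9) {
        stop_mscoal("hybrid edge ", hyb$label[i],
                    ": donor and recipient nodes must share the same age")
      }
      if (nkids[d] != 1L || nkids[r] != 1L) {
        stop_mscoal("hybrid edge ", hyb$label[i],
                    ": donor and recipient must be degree-two branch nodes")
      }
    }
  }
  # degree-2 nodes are only allowed as hybrid attachment points
  deg2 <- nodes$name[nkids[nodes$name] == 1]
  stray <- setdiff(deg2, c(hyb$donor, hyb$recipient))
  if (length(stray)) {
    stop_mscoal("degree-two node(s) not part of a hybrid edge: ",
                paste(stray, collapse = ", "))
  }

  bands <- net$bands
  if (nrow(bands)) {
    spans <- population_spans(net)
    for (i in seq_len(nrow(bands))) {
      d <- bands$donor[i]; r <- bands$recipient[i]
      if (d == r) stop_mscoal("migration band donor equals recipient")
      if (!all(c(d, r) %in% nodes$name)) {
        stop_mscoal("migration band references unknown population")
      }
      if (bands$rate[i] < 0) stop_mscoal("migration rate must be >= 0")
      lo <- max(spans$lo[spans$pop == d], spans$lo[spans$pop == r])
      hi <- min(spans$hi[spans$pop == d], spans$hi[spans$pop == r])
      if (is.na(net$bands$start[i])) net$bands$start[i] <- lo
      if (is.na(net$bands$end[i])) net$bands$end[i] <- hi
      if (net$bands$start[i] < lo - 1e-12 || net$bands$end[i] > hi + 1e-12 ||
          net$bands$end[i] <= net$bands$start[i]) {
        stop_mscoal("migration band ", d, "->", r,
                    " is empty or outside the populations' coexistence")
      }
    }
  }
  net
}

#' @export
print.species_network <- function(x, ...) {
  tips <- network_tips(x)
  cat("<species_network> ", length(tips), " tips (",
      paste(tips, collapse = ", "), "), root age ",
      format(max(x$nodes$age)), "\n", sep = "")
  if (nrow(x$hybrids)) {
    cat("  introgression edges:\n")
    for (i in seq_len(nrow(x$hybrids))) {
      cat(sprintf("    %s -> %s at tau = %g, phi = %g\n",
                  x$hybrids$donor[i], x$hybrids$recipient[i],
                  x$nodes$age[x$nodes$name == x$hybrids$recipient[i]],
                  x$hybrids$phi[i]))
    }
  }
  if (nrow(x$bands)) {
    cat("  migration bands:\n")
    for (i in seq_len(nrow(x$bands))) {
      cat(sprintf("    %s -> %s, M = %g over (%g, %g]\n",
                  x$bands$donor[i], x$bands$recipient[i], x$bands$rate[i],
                  x$bands$start[i], x$bands$end[i]))
    }
  }
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.species_network <- function(x, ...) x$nodes

network_root <- function(net) net$nodes$name[is.na(net$nodes$parent)]

network_children <- function(net, name) {
  net$nodes$name[!is.na(net$nodes$parent) & net$nodes$parent == name]
}

#' Tip (sampled species) names of a network
#'
#' @param net A `species_network`.
#' @param include_ghost Keep unsampled ghost tips?
#' @return Character vector of tip names.
#' @export
network_tips <- function(net, include_ghost = TRUE) {
  nkids <- table(factor(net$nodes$parent, levels = net$nodes$name))
  tips <- net$nodes$name[nkids[net$nodes$name] == 0]
  if (!include_ghost) tips <- setdiff(tips, net$nodes$name[net$nodes$ghost])
  tips
}

# population = branch above each node; lifespan (age(node), age(parent)],
# the root population is unbounded above
population_spans <- function(net) {
  age <- stats::setNames(net$nodes$age, net$nodes$name)
  hi <- ifelse(is.na(net$nodes$parent), Inf, unname(age[net$nodes$parent]))
  tibble::tibble(pop = net$nodes$name, lo = net$nodes$age, hi = hi,
                 theta = net$nodes$theta)
}

#' Collapse a network to its major species tree
#'
#' Removes introgression edges and migration bands, splices out the
#' degree-two hybrid attachment nodes, and optionally drops ghost tips.
#' This is the tree an analysis that ignores gene flow assumes.
#'
#' @param net A `species_network`.
#' @param drop_ghost Drop unsampled ghost tips (and any resulting degree-two
#'   nodes)? Default `TRUE`.
#' @return A `species_network` with no hybrid edges or bands.
#' @export
major_tree <- function(net, drop_ghost = TRUE) {
  nodes <- net$nodes
  if (drop_ghost) {
    # original sampled tips stay; ghost tips and any internal nodes left
    # childless by their removal are pruned
    keep_tips <- network_tips(net, include_ghost = FALSE)
    repeat {
      nkids <- table(factor(nodes$parent, levels = nodes$name))
      dead <- setdiff(nodes$name[nkids[nodes$name] == 0], keep_tips)
      if (!length(dead)) break
      nodes <- nodes[!(nodes$name %in% dead), ]
    }
  }
  # splice out degree-two nodes (hybrid attachment points, or nodes left
  # behind by ghost removal)
  repeat {
    nkids <- table(factor(nodes$parent, levels = nodes$name))
    deg2 <- nodes$name[nkids[nodes$name] == 1 & !is.na(nodes$parent)]
    if (!length(deg2)) {
      # a degree-one root is replaced by its child subtree's root
      root <- nodes$name[is.na(nodes$parent)]
      if (nkids[root] == 1L) {
        child <- nodes$name[!is.na(nodes$parent) & nodes$parent == root]
        nodes <- nodes[nodes$name != root, ]
        nodes$parent[nodes$name == child] <- NA
        next
      }
      break
    }
    v <- deg2[1]
    child <- nodes$name[!is.na(nodes$parent) & nodes$parent == v]
    nodes$parent[nodes$name == child] <- nodes$parent[nodes$name == v]
    nodes <- nodes[nodes$name != v, ]
  }
  species_network(nodes)
}
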