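# Internal population-graph view of a species network.
#
# Every node owns the population (branch) directly above it; the root node
# owns the unbounded root population. Backward in time a lineage leaving the
# top of a population either enters its parent population deterministically,
# or -- when the parent node is the recipient side of an introgression edge --
# chooses the donor-side population with probability phi. Branches are
# half-open intervals (child_age, parent_age]: an event exactly at a node
# belongs to the parent population.

# cached wrapper: the graph is deterministic in the network, so compute it
# once per network object
net_pop_graph <- function(net) {
  cache <- attr(net, "pg_cache")
  if (is.null(cache)) {
    # no cache environment on this copy; build directly
    return(build_pop_graph(net))
  }
  if (is.null(cache$pg)) cache$pg <- build_pop_graph(net)
  cache$pg
}

build_pop_graph <- function(net) {
  nodes <- net$nodes
  hyb <- net$hybrids
  nm <- nodes$name
  age <- stats::setNames(nodes$age, nm)
  parent <- stats::setNames(nodes$parent, nm)
  pop_id <- stats::setNames(seq_along(nm), nm)

  # tau parameters: one per speciation node, one per hybrid pair
  is_hyb_node <- nm %in% c(hyb$donor, hyb$recipient)
  nkids <- table(factor(nodes$parent, levels = nm))
  is_tip <- nkids[nm] == 0
  tau_of_node <- stats::setNames(rep(NA_character_, length(nm)), nm)
  for (x in nm[!is_tip & !is_hyb_node]) tau_of_node[x] <- paste0("tau_", x)
  if (nrow(hyb)) {
    for (i in seq_len(nrow(hyb))) {
      p <- paste0("tau_", hyb$recipient[i])
      tau_of_node[hyb$recipient[i]] <- p
      tau_of_node[hyb$donor[i]] <- p
    }
  }
  tau_params <- unique(stats::na.omit(tau_of_node))
  tau_value <- vapply(tau_params, function(p) {
    unname(age[names(tau_of_node)[which(tau_of_node == p)[1]]])
  }, 0)

  recip_parent <- if (nrow(hyb)) stats::setNames(seq_len(nrow(hyb)), hyb$recipient) else
    stats::setNames(integer(), character())

  trans <- character(length(nm))
  to1 <- to2 <- rep(NA_integer_, length(nm))
  phi_param <- rep(NA_character_, length(nm))
  for (i in seq_along(nm)) {
    x <- nm[i]
    p <- parent[x]
    if (is.na(p)) {
      trans[i] <- "root"
    } else if (p %in% names(recip_parent)) {
      k <- recip_parent[[p]]
      trans[i] <- "choice"
      to1[i] <- pop_id[[hyb$donor[k]]]   # donor path, probability phi
      to2[i] <- pop_id[[p]]              # stay, probability 1 - phi
      phi_param[i] <- paste0("phi_", hyb$recipient[k])
    } else {
      trans[i] <- "single"
      to1[i] <- pop_id[[p]]
    }
  }

  pops <- tibble::tibble(
    id = seq_along(nm),
    pop = nm,
    lo_age = unname(age[nm]),
    hi_age = ifelse(is.na(parent[nm]), Inf, unname(age[parent[nm]])),
    lo_tau = unname(tau_of_node[nm]),
    hi_tau = ifelse(is.na(parent[nm]), NA_character_,
                    unname(tau_of_node[parent[nm]])),
    theta = nodes$theta,
    trans = trans,
    to1 = to1,
    to2 = to2,
    phi = phi_param
  )

  phis <- if (nrow(hyb)) {
    tibble::tibble(param = paste0("phi_", hyb$recipient), value = hyb$phi,
                   label = hyb$label,
                   choice_pop = unname(pop_id[
                     nodes$name[match(hyb$recipient, nodes$parent)]]))
  } else {
    tibble::tibble(param = character(), value = numeric(),
                   label = character(), choice_pop = integer())
  }

  bands <- if (nrow(net$bands)) {
    tibble::tibble(
      donor = unname(pop_id[net$bands$donor]),
      recipient = unname(pop_id[net$bands$recipient]),
      rate = net$bands$rate,
      start = net$bands$start,
      end = net$bands$end
    )
  } else {
    tibble::tibble(donor = integer(), recipient = integer(), rate = numeric(),
                   start = numeric(), end = numeric())
  }

  list(
    pops = pops,
    tau = tibble::tibble(param = tau_params, value = unname(tau_value)),
    phi = phis,
    bands = bands,
    tip_pop = pop_id[nm[is_tip]],
    root_tau = unname(tau_of_node[nm[is.na(parent[nm])]])
  )
}

# population id of the choice pop for each hybrid: the pop whose top is the
# recipient node (i.e. the single tree child of the recipient node)
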