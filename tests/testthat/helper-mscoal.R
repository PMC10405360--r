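# Shared fixtures: tiny networks and configurations built in code.

# single population (one node that is tip and root at once)
one_pop_net <- function(theta = 0.01) {
  species_network(tibble::tibble(name = "A", parent = NA_character_,
                                 age = 0, theta = theta))
}

two_species_net <- function(tau = 0.01, theta = 0.01) {
  species_network(tibble::tibble(
    name = c("A", "B", "r"), parent = c("r", "r", NA),
    age = c(0, 0, tau), theta = theta
  ))
}

# a random ultrametric tree with one random introgression edge, for
# serialization property tests
random_network <- function(ntip = 5, with_hybrid = TRUE) {
  tips <- LETTERS[seq_len(ntip)]
  nodes <- tibble::tibble(name = tips, parent = NA_character_, age = 0,
                          theta = stats::runif(ntip, 0.001, 0.05))
  act <- tips
  age <- 0
  k <- 0
  while (length(act) > 1) {
    k <- k + 1
    age <- age + stats::rexp(1, 50)
    pair <- sample(act, 2)
    anc <- paste0("n", k)
    nodes$parent[nodes$name %in% pair] <- anc
    nodes <- dplyr::bind_rows(nodes, tibble::tibble(
      name = anc, parent = NA_character_, age = age,
      theta = stats::runif(1, 0.001, 0.05)
    ))
    act <- c(setdiff(act, pair), anc)
  }
  net <- species_network(nodes)
  if (!with_hybrid) return(net)
  # insert a hybrid edge between two coexisting tip branches
  spans <- population_spans(net)
  tipsp <- spans[spans$pop %in% tips, ]
  pair <- sample(tips, 2)
  tmax <- min(tipsp$hi[tipsp$pop %in% pair])
  th <- stats::runif(1, 0.2, 0.8) * tmax
  splice <- function(nodes, tip, nm) {
    old <- nodes$parent[nodes$name == tip]
    nodes$parent[nodes$name == tip] <- nm
    dplyr::bind_rows(nodes, tibble::tibble(
      name = nm, parent = old, age = th,
      theta = stats::runif(1, 0.001, 0.05)
    ))
  }
  nodes <- net$nodes
  nodes <- splice(nodes, pair[1], "hx")
  nodes <- splice(nodes, pair[2], "gx")
  species_network(nodes, hybrids = tibble::tibble(
    label = "H1", donor = "gx", recipient = "hx",
    phi = stats::runif(1)
  ))
}

# networks compared up to row order
expect_network_equal <- function(a, b) {
  m <- match(a$nodes$name, b$nodes$name)
  expect_false(anyNA(m))
  expect_identical(a$nodes$parent, b$nodes$parent[m])
  expect_equal(a$nodes$age, b$nodes$age[m], tolerance = 1e-12)
  expect_equal(a$nodes$theta, b$nodes$theta[m], tolerance = 1e-12)
  expect_equal(dplyr::arrange(as.data.frame(a$hybrids), label),
               dplyr::arrange(as.data.frame(b$hybrids), label),
               tolerance = 1e-12)
}

quick_mcmc <- function(seed = 1, burnin = 500, nsamples = 500, thin = 2) {
  mcmc_config(burnin = burnin, nsamples = nsamples, thin = thin, seed = seed)
}

rinvgamma <- function(n, a, b) 1 / stats::rgamma(n, a, rate = b)

# brute-force enumeration over all internal-node state assignments
enum_loglik <- function(gt, locus) {
  nd <- gt$nodes
  ntip <- sum(!is.na(nd$label))
  n <- nrow(nd)
  code <- match(locus$alignment[nd$label[seq_len(ntip)], , drop = FALSE],
                c("A", "C", "G", "T"))
  dim(code) <- c(ntip, ncol(locus$alignment))
  nint <- n - ntip
  total <- 0
  ll <- 0
  for (site in seq_len(ncol(code))) {
    site_sum <- 0
    for (assign in seq_len(4^nint) - 1) {
      states <- c(code[, site],
                  (assign %/% 4^(seq_len(nint) - 1)) %% 4 + 1)
      pr <- 0.25
      for (v in seq_len(n)) {
        if (!is.na(nd$parent[v])) {
          d <- nd$age[nd$parent[v]] - nd$age[v]
          pr <- pr * jc69_transition(d)[states[nd$parent[v]], states[v]]
        }
      }
      site_sum <- site_sum + pr
    }
    ll <- ll + log(site_sum)
  }
  ll
}

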