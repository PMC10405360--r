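test_that("JC69 transition matrix takes its closed-form values", {
  expect_equal(jc69_transition(0), diag(4), ignore_attr = TRUE)
  expect_equal(jc69_transition(1e6), matrix(0.25, 4, 4), ignore_attr = TRUE,
               tolerance = 1e-12)
  m <- jc69_transition(0.01)
  expect_equal(m[1, 1], 0.25 + 0.75 * exp(-0.04 / 3))
  expect_equal(round(m[1, 1], 5), 0.99007)
  expect_equal(rowSums(m), rep(1, 4), ignore_attr = TRUE)
  expect_error(jc69_transition(-0.1), "non-negative")
})

make_two_tip_tree <- function(t) {
  gt <- simulate_gene_tree(two_species_net(tau = t / 2),
                           sample_config(c(A = 1, B = 1)), seed = 1)
  gt$nodes$age[3] <- t
  gt$nodes$pop[3] <- "r"
  gt
}

test_that("two-tip likelihood matches the closed form", {
  t <- 0.02
  gt <- make_two_tip_tree(t)
  same <- locus_data(c(a1 = "A", b1 = "A"))
  diffr <- locus_data(c(a1 = "A", b1 = "C"))
  e <- exp(-8 * t / 3)
  expect_equal(locus_loglik(gt, same), log(0.25 * (0.25 + 0.75 * e)))
  expect_equal(locus_loglik(gt, diffr), log(0.25 * (0.25 - 0.25 * e)))
})

test_that("pruning equals brute-force enumeration on small trees", {
  set.seed(13)
  for (rep in 1:6) {
    ntip <- sample(3:4, 1)
    counts <- stats::setNames(c(ntip - 1, 1), c("A", "B"))
    gt <- simulate_gene_tree(two_species_net(tau = 0.02),
                             sample_config(counts))
    ld <- evolve_jc69(gt, 3)
    expect_equal(locus_loglik(gt, ld), enum_loglik(gt, ld),
                 tolerance = 1e-10)
  }
})

test_that("likelihood of an empty alignment is zero and invariant to tip order", {
  gt <- simulate_gene_tree(two_species_net(), sample_config(c(A = 2, B = 2)),
                           seed = 14)
  ld <- evolve_jc69(gt, 50, seed = 15)
  empty <- ld
  empty$alignment <- ld$alignment[, 0, drop = FALSE]
  expect_equal(locus_loglik(gt, empty), 0)
  shuffled <- ld
  shuffled$alignment <- ld$alignment[c(3, 1, 4, 2), , drop = FALSE]
  expect_equal(locus_loglik(gt, shuffled), locus_loglik(gt, ld))
  bad <- ld
  rownames(bad$alignment)[1] <- "zz"
  expect_error(locus_loglik(gt, bad), "match")
})

test_that("single-population gene-tree density is the textbook exponential", {
  net <- one_pop_net(theta = 0.02)
  gt <- simulate_gene_tree(net, sample_config(c(A = 2)), seed = 16)
  t <- gt$nodes$age[3]
  expect_equal(gene_tree_log_density(gt, net),
               log(2 / 0.02) - 2 * t / 0.02, tolerance = 1e-12)
})

test_that("hybrid choices contribute log(phi) vs log(1 - phi)", {
  # sample one A lineage (plus one C): the donor and recipient paths above
  # tau_h hold no other lineages, so flipping the choice changes the density
  # by exactly the log ratio of the path probabilities
  net <- scenario_network("sister", 0.01, rate = 0.2, mode = "msci")
  cfg <- sample_config(c(A = 1, C = 1))
  set.seed(17)
  found <- FALSE
  for (i in 1:50) {
    gt <- simulate_gene_tree(net, cfg)
    if (any(gt$choices$node == 1)) { found <- TRUE; break }
  }
  expect_true(found)
  flipped <- gt
  i <- which(flipped$choices$node == 1)[1]
  old <- flipped$choices$choice[i]
  flipped$choices$choice[i] <- if (old == "donor") "recipient" else "donor"
  ratio <- if (old == "donor") log(0.8) - log(0.2) else log(0.2) - log(0.8)
  expect_equal(gene_tree_log_density(flipped, net) -
                 gene_tree_log_density(gt, net), ratio, tolerance = 1e-10)
})

test_that("gene-tree density integrates to one (2 and 3 lineages)", {
  net <- one_pop_net(theta = 0.01)
  gt <- simulate_gene_tree(net, sample_config(c(A = 2)), seed = 18)
  f2 <- function(t) {
    vapply(t, function(ti) {
      g <- gt
      g$nodes$age[3] <- ti
      exp(gene_tree_log_density(g, net))
    }, 0)
  }
  expect_equal(stats::integrate(f2, 0, Inf)$value, 1, tolerance = 1e-6)

  gt3 <- simulate_gene_tree(net, sample_config(c(A = 3)), seed = 19)
  # order the two coalescences t1 < t2; integrate over both, summing over the
  # 3 possible first pairs
  f3 <- function(t1, t2) {
    g <- gt3
    o <- order(g$nodes$age[4:5])
    g$nodes$age[4:5][o] <- c(t1, t2)
    exp(gene_tree_log_density(g, net))
  }
  inner <- function(t1) {
    vapply(t1, function(a) {
      stats::integrate(function(t2) {
        vapply(t2, function(b) f3(a, b), 0)
      }, a, Inf)$value
    }, 0)
  }
  # 3 distinct labelled topologies for the first coalescence
  expect_equal(3 * stats::integrate(inner, 0, Inf)$value, 1,
               tolerance = 1e-4)
})

test_that("the compiled likelihood/density core agrees with the R reference", {
  net <- scenario_network("nonsister", 0.01, rate = 0.2, mode = "msci")
  cfg <- sample_config(c(A = 2, B = 2, C = 2, D = 2))
  pri <- prior_spec(0.01, 0.03)
  set.seed(20)
  gts <- lapply(1:12, function(i) simulate_gene_tree(net, cfg))
  loci <- lapply(gts, evolve_jc69, L = 120)
  got <- mscoal:::eval_state_core(loci, gts, cfg, net, pri)
  want_lnl <- vapply(seq_along(gts),
                     function(i) locus_loglik(gts[[i]], loci[[i]]), 0)
  want_dens <- vapply(gts, gene_tree_log_density, 0, net = net)
  expect_equal(got$lnl, want_lnl, tolerance = 1e-9)
  expect_equal(got$logdens, want_dens, tolerance = 1e-9)
})
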